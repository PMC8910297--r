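#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_rect geom_hline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a binding fit
#'
#' Observed combined shift distances and the fitted depletion isotherm per
#' residue, against total ligand concentration.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  obs <- object$data
  curves <- obs |>
    group_by(.data$residue_id) |>
    summarise(pt = first(.data$protein_total_uM),
              lmax = max(.data$ligand_total_uM), .groups = "drop")
  grid <- curves |>
    dplyr::reframe(
      ligand_total_uM = exp(seq(log(.data$lmax / 200), log(.data$lmax),
                                length.out = 80)),
      protein_total_uM = .data$pt,
      .by = "residue_id"
    ) |>
    mutate(d_ppm = binding_isotherm(
      .data$protein_total_uM, .data$ligand_total_uM, object$kd_hat,
      unname(object$dmax_hat[as.character(.data$residue_id)])
    ))
  ggplot(obs, aes(x = .data$ligand_total_uM, y = .data$d_ppm)) +
    geom_line(data = grid, color = "steelblue") +
    geom_point(size = 1) +
    facet_wrap(~residue_id, scales = "free_y") +
    labs(
      x = "total ligand (uM)", y = "combined shift distance (ppm)",
      title = sprintf("%s fit: Kd = %.3g +/- %.2g uM",
                      object$method, object$kd_hat, object$kd_se)
    ) +
    theme_minimal()
}

#' Per-residue perturbation bar plot
#'
#' Final-point combined shift distance by residue, colored by perturbation
#' class; the standard binding-site mapping figure.
#'
#' @param classification Output of [classify_perturbed()].
#' @return A ggplot object.
#' @export
plot_perturbation <- function(classification) {
  ggplot(filter(classification, .data$class != "excluded"),
         aes(x = .data$residue_id, y = .data$d_final, fill = .data$class)) +
    geom_col() +
    labs(x = "residue", y = expression(Delta * d ~ "(ppm)"),
         fill = "class") +
    theme_minimal()
}

#' Plot a fluorescence-anisotropy fit
#'
#' @param object An `fa_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fa_fit
#' @export
autoplot.fa_fit <- function(object, ...) {
  obs <- object$data
  lmax <- max(obs$ligand_total_uM)
  grid <- tibble(ligand_total_uM = seq(0, lmax, length.out = 200))
  grid$anisotropy <- .fa_model(
    c(object$r_free_hat, object$r_bound_hat, object$kd_hat),
    grid$ligand_total_uM, object$protein_total_uM, object$deplete
  )
  ggplot(obs, aes(x = .data$ligand_total_uM, y = .data$anisotropy)) +
    geom_line(data = grid, color = "steelblue") +
    geom_point() +
    labs(x = "total ligand (uM)", y = "anisotropy",
         title = sprintf("one-site fit: Kd = %.3g +/- %.2g uM",
                         object$kd_hat, object$kd_se)) +
    theme_minimal()
}

#' Plot a distance trace with its bound-state segmentation
#'
#' @param object A `distance_trace`.
#' @param segments Optional `bound_segments` to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot distance_trace
#' @export
autoplot.distance_trace <- function(object, segments = NULL, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$t_ns, y = .data$distance_A)) +
    geom_line(linewidth = 0.2) +
    labs(x = "time (ns)", y = "protein-ligand distance (A)") +
    theme_minimal()
  if (!is.null(segments)) {
    shade <- as_tibble(segments)
    p <- p +
      geom_rect(
        data = shade,
        aes(xmin = .data$start_ns, xmax = .data$end_ns),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
        inherit.aes = FALSE
      ) +
      geom_hline(yintercept = c(attr(segments, "threshold_low"),
                                attr(segments, "threshold_high")),
                 linetype = "dashed", color = "grey40")
  }
  p
}
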