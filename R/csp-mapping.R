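#' Combined amide chemical-shift distance
#'
#' The scalar perturbation measure used throughout chemical-shift mapping:
#' the root-mean-square of the 1H shift change and the scaled 15N shift
#' change,
#' \deqn{d = \sqrt{\tfrac{1}{2}\left[\Delta\delta_H^2 +
#'   (\alpha\,\Delta\delta_N)^2\right]}}{d = sqrt((dH^2 + (alpha dN)^2)/2)}
#' with a single global nitrogen scaling factor `alpha` (default 0.14, the
#' conventional ratio of amide 1H to 15N shift dispersions).
#'
#' @param delta_H 1H shift difference(s), ppm.
#' @param delta_N 15N shift difference(s), ppm.
#' @param alpha Nitrogen scaling factor, dimensionless, > 0.
#' @return Combined shift distance(s) in ppm, same length as the inputs.
#'   `NA`/`NaN` inputs propagate.
#' @examples
#' combined_shift_distance(0.1, 0.5) # 0.0863
#' @export
combined_shift_distance <- function(delta_H, delta_N, alpha = 0.14) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    abort("alpha must be a single positive number")
  }
  sqrt((delta_H^2 + (alpha * delta_N)^2) / 2)
}

#' Per-residue chemical-shift perturbation profiles
#'
#' For every residue observable at the apo reference point, computes the
#' combined shift distance of each titration point relative to the reference.
#' Residues whose reference peak is overlapped or missing carry no usable
#' perturbation information and are dropped; points where a residue is not
#' `"ok"` yield `NA` with `ok = FALSE`.
#'
#' @param dataset A `titration_data` tibble (see [as_titration_data()]).
#' @param alpha Nitrogen scaling factor passed to
#'   [combined_shift_distance()].
#' @return A `csp_profiles` tibble with columns `residue_id`, `residue_name`,
#'   `point_index`, `protein_total_uM`, `ligand_total_uM`, `d_ppm`, `ok`;
#'   attributes `alpha` and `reference_index`.
#' @export
csp_profiles <- function(dataset, alpha = 0.14) {
  validate_titration_data(dataset)
  pts <- titration_points(dataset)
  ref_index <- pts$point_index[1]
  ref <- dataset |>
    filter(.data$point_index == ref_index, .data$quality == "ok") |>
    select("residue_id", dH_ref = "delta_H_ppm", dN_ref = "delta_N_ppm")
  out <- as_tibble(dataset) |>
    inner_join(ref, by = "residue_id") |>
    mutate(
      ok = .data$quality == "ok",
      d_ppm = ifelse(
        .data$ok,
        combined_shift_distance(.data$delta_H_ppm - .data$dH_ref,
                                .data$delta_N_ppm - .data$dN_ref, alpha),
        NA_real_
      )
    ) |>
    select("residue_id", "residue_name", "point_index",
           "protein_total_uM", "ligand_total_uM", "d_ppm", "ok") |>
    arrange(.data$residue_id, .data$point_index)
  structure(out, alpha = alpha, reference_index = ref_index,
            class = c("csp_profiles", class(tibble())))
}

#' Classify and rank perturbed residues
#'
#' Ranks residues by their combined shift distance at the final titration
#' point (largest bound population) and assigns perturbation classes. The
#' default `sd_threshold` method computes the mean \eqn{\mu} and standard
#' deviation \eqn{\sigma} of the final-point distances over all classifiable
#' residues and uses the ladder: `strong` above \eqn{\mu + 2\sigma},
#' `intermediate` above \eqn{\mu + \sigma}, `minor` above \eqn{\mu}, else
#' `unperturbed`. `fixed_cutoffs` applies absolute ppm cutoffs instead.
#' Residues not observable (`ok = FALSE`) at the reference or final point are
#' `excluded` and unranked.
#'
#' @param profiles A `csp_profiles` tibble from [csp_profiles()].
#' @param method `"sd_threshold"` (default) or `"fixed_cutoffs"`.
#' @param cutoffs For `fixed_cutoffs`: named numeric vector
#'   `c(strong =, intermediate =, minor =)` of lower bounds in ppm.
#' @return A tibble with `residue_id`, `residue_name`, `d_final`, `class`
#'   (factor: strong, intermediate, minor, unperturbed, excluded) and `rank`
#'   (descending `d_final`, ties broken by residue number; `NA` for excluded).
#' @export
classify_perturbed <- function(profiles,
                               method = c("sd_threshold", "fixed_cutoffs"),
                               cutoffs = NULL) {
  method <- match.arg(method)
  final_index <- max(profiles$point_index)
  finals <- profiles |>
    filter(.data$point_index == final_index) |>
    select("residue_id", "residue_name", d_final = "d_ppm", "ok")
  classifiable <- finals |> filter(.data$ok)
  if (nrow(classifiable) < 3) {
    abort("classification needs at least 3 classifiable residues")
  }
  if (method == "sd_threshold") {
    mu <- mean(classifiable$d_final)
    sigma <- sd(classifiable$d_final)
    thr <- c(strong = mu + 2 * sigma, intermediate = mu + sigma, minor = mu)
  } else {
    if (is.null(cutoffs) ||
        !all(c("strong", "intermediate", "minor") %in% names(cutoffs))) {
      abort("fixed_cutoffs needs cutoffs = c(strong=, intermediate=, minor=)")
    }
    thr <- cutoffs[c("strong", "intermediate", "minor")]
  }
  cls <- function(d) {
    dplyr::case_when(
      d > thr[["strong"]] ~ "strong",
      d > thr[["intermediate"]] ~ "intermediate",
      d > thr[["minor"]] ~ "minor",
      TRUE ~ "unperturbed"
    )
  }
  out <- finals |>
    mutate(
      class = ifelse(.data$ok, cls(.data$d_final), "excluded"),
      class = factor(.data$class,
                     levels = c("strong", "intermediate", "minor",
                                "unperturbed", "excluded"))
    ) |>
    select(-"ok")
  ranked <- out$class != "excluded"
  ord <- order(-out$d_final[ranked], out$residue_id[ranked])
  out$rank <- NA_integer_
  out$rank[which(ranked)[ord]] <- seq_len(sum(ranked))
  arrange(out, .data$residue_id)
}

#' Top-ranked perturbed residues
#'
#' Convenience selector for the residues to carry into a global binding fit:
#' the `n` residues with the largest final-point combined shift distance.
#'
#' @param profiles A `csp_profiles` tibble.
#' @param n Number of residues (default 9, a typical panel for a
#'   simultaneous fit).
#' @return Integer vector of residue ids.
#' @export
top_perturbed_residues <- function(profiles, n = 9) {
  classification <- classify_perturbed(profiles)
  ranked <- classification |> filter(!is.na(.data$rank)) |>
    arrange(.data$rank)
  head(ranked$residue_id, n)
}
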