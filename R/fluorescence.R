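#' Assemble a fluorescence-anisotropy titration series
#'
#' A tibble with one row per titration point: `ligand_total_uM` (nondecreasing),
#' `anisotropy` (dimensionless, within \[-0.2, 0.4\]), and optionally
#' `intensity` (a.u.), `A_ex`/`A_em` (absorbances at the excitation/emission
#' wavelengths) and `volume_added_uL`. The protein concentration is carried
#' as an attribute.
#'
#' @param x Data frame with the columns above.
#' @param protein_total Total protein concentration, uM.
#' @return A validated `fa_series` tibble.
#' @export
fa_series <- function(x, protein_total) {
  x <- as_tibble(x)
  for (col in c("ligand_total_uM", "anisotropy")) {
    if (!col %in% names(x)) {
      abort(paste0("fa_series is missing required column: ", col))
    }
  }
  if (!is.numeric(protein_total) || length(protein_total) != 1L ||
      protein_total <= 0) {
    abort("protein_total must be a single positive concentration in uM")
  }
  if (is.unsorted(x$ligand_total_uM)) {
    abort("ligand_total_uM must be nondecreasing")
  }
  if (any(x$anisotropy < -0.2 | x$anisotropy > 0.4, na.rm = TRUE)) {
    abort("anisotropy outside the physical range [-0.2, 0.4]")
  }
  structure(x, protein_total_uM = protein_total,
            class = c("fa_series", class(tibble())))
}

#' Inner-filter correction of fluorescence intensities
#'
#' Standard half-path-length correction for attenuation of the excitation and
#' emission beams by sample absorbance:
#' \deqn{F_{corr} = F_{obs}\cdot 10^{(A_{ex}+A_{em})/2}}
#'
#' @param f_obs Observed intensity (a.u.).
#' @param a_ex Absorbance at the excitation wavelength (>= 0).
#' @param a_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected intensity, same length as `f_obs`.
#' @examples
#' inner_filter_correct(100, 0.1, 0.1) # 125.89
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0) || any(a_em < 0)) abort("absorbances must be >= 0")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Dilution correction of a titration readout
#'
#' Rescales readings for the dilution caused by cumulative ligand additions:
#' each value is multiplied by
#' `(initial_volume + cumulative_added) / initial_volume`.
#'
#' @param values Readings to correct, one per titration point.
#' @param volumes_added Volume added at each point (same units as
#'   `initial_volume`); incremental, not cumulative.
#' @param initial_volume Starting sample volume (> 0).
#' @return Corrected values.
#' @export
dilution_correct <- function(values, volumes_added, initial_volume) {
  if (initial_volume <= 0) abort("initial_volume must be > 0")
  if (any(volumes_added < 0)) abort("volumes_added must be >= 0")
  if (length(volumes_added) != length(values)) {
    abort("values and volumes_added must have the same length")
  }
  values * (initial_volume + cumsum(volumes_added)) / initial_volume
}

# anisotropy predicted by the one-site model
.fa_model <- function(par, l, pt, deplete) {
  r_free <- par[1]; r_bound <- par[2]; kd <- par[3]
  fb <- if (deplete) fraction_bound(pt, l, kd) else l / (kd + l)
  r_free + (r_bound - r_free) * fb
}

#' One-site specific-binding fit of an anisotropy titration
#'
#' Fits `r_free`, `r_bound` and `Kd` by least squares. Without depletion the
#' bound fraction is the hyperbola `L/(Kd + L)`; with `deplete = TRUE` it is
#' the exact 1:1 quadratic ([fraction_bound()]) with the protein as the
#' observed species, appropriate when the protein concentration is not
#' negligible against `Kd`. The two agree as `protein_total/Kd` tends to 0.
#'
#' @param series An [fa_series()] tibble (>= 5 points, spanning either two
#'   orders of magnitude in ligand or most of the saturation curve).
#' @param deplete Use the exact depletion quadratic (default `TRUE`).
#' @return An `fa_fit` object: `kd_hat` (uM), `kd_se`, `r_free_hat`,
#'   `r_bound_hat`, their SEs, `rss`, `converged`, `n_obs`,
#'   `saturation_fraction` (share of the fitted amplitude covered by the
#'   data; below 0.3 raises `saturation_warning`). See [tidy.fa_fit()],
#'   [autoplot.fa_fit()].
#' @export
fit_one_site <- function(series, deplete = TRUE) {
  stopifnot(inherits(series, "fa_series") || is.data.frame(series))
  pt <- attr(series, "protein_total_uM") %||% 0
  if (deplete && pt <= 0) {
    abort("deplete = TRUE needs a protein_total attribute; build the series with fa_series()")
  }
  obs <- as_tibble(series) |>
    filter(is.finite(.data$anisotropy), is.finite(.data$ligand_total_uM))
  if (nrow(obs) < 5) abort("fit_one_site needs at least 5 points")
  l <- obs$ligand_total_uM
  r <- obs$anisotropy
  lpos <- l[l > 0]
  span_decades <- if (length(lpos) > 1) log10(max(lpos) / min(lpos)) else 0
  par0 <- c(r_free = r[1], r_bound = tail(r, 1), kd = median(lpos))
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = c(-0.2, -0.2, 1e-9), upper = c(0.4, 0.4, Inf),
    fn = function(p) r - .fa_model(p, l, pt, deplete),
    control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-12,
                                         maxiter = 500)
  )
  par <- fit$par
  res <- r - .fa_model(par, l, pt, deplete)
  rss <- sum(res^2)
  n <- length(r)
  # covariance SE via finite-difference Jacobian
  J <- matrix(0, n, 3)
  for (j in 1:3) {
    h <- max(1e-7 * abs(par[j]), 1e-10)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (.fa_model(up, l, pt, deplete) -
                 .fa_model(dn, l, pt, deplete)) / (up[j] - dn[j])
  }
  se <- tryCatch({
    cov <- chol2inv(chol(crossprod(J))) * rss / max(n - 3, 1)
    sqrt(diag(cov))
  }, error = function(e) rep(Inf, 3))
  amp <- par[2] - par[1]
  fitted_r <- .fa_model(par, l, pt, deplete)
  sat_frac <- if (abs(amp) > 0) {
    (max(fitted_r) - min(fitted_r)) / abs(amp)
  } else {
    0
  }
  sat_warn <- sat_frac < 0.3
  if (sat_warn) {
    warn(sprintf(
      "saturation not approached: data cover %.0f%% of the fitted amplitude",
      100 * sat_frac
    ))
  }
  structure(
    list(
      kd_hat = unname(par[3]), kd_se = se[3],
      r_free_hat = unname(par[1]), r_free_se = se[1],
      r_bound_hat = unname(par[2]), r_bound_se = se[2],
      rss = rss, converged = fit$info %in% 1:4, n_obs = n,
      deplete = deplete, protein_total_uM = pt,
      span_decades = span_decades,
      saturation_fraction = sat_frac, saturation_warning = sat_warn,
      data = mutate(obs, fitted = fitted_r, residual = res)
    ),
    class = "fa_fit"
  )
}

#' Test for the presence of specific binding
#'
#' Operationalizes the visual "the response follows a straight line" verdict:
#' both a straight line and the one-site saturating model are fitted to the
#' response, and specific binding is declared only when the saturating model
#' reduces the residual sum of squares enough to pass an F-test at `level`
#' (one extra parameter) *and* the fitted `Kd` does not exceed the largest
#' tested ligand concentration. A flat (constant) response short-circuits to
#' "no specific binding".
#'
#' @param series An [fa_series()] tibble with >= 6 points.
#' @param response Column to test, `"anisotropy"` (default) or
#'   `"intensity"`.
#' @param level F-test significance level (default 0.05).
#' @param deplete Passed to the saturating fit; default `FALSE` (the test
#'   regime is weak/absent binding where depletion is negligible).
#' @return An `fa_specificity` object: `specific` (logical), `linear_rss`,
#'   `saturating_rss`, `p_value`, `kd_hat`, and a human-readable
#'   `criterion`.
#' @export
test_specific_binding <- function(series, response = c("anisotropy", "intensity"),
                                  level = 0.05, deplete = FALSE) {
  response <- match.arg(response)
  obs <- as_tibble(series)
  if (!response %in% names(obs)) {
    abort(paste0("series has no `", response, "` column"))
  }
  obs <- filter(obs, is.finite(.data[[response]]),
                is.finite(.data$ligand_total_uM))
  n <- nrow(obs)
  if (n < 6) abort("test_specific_binding needs at least 6 points")
  y <- obs[[response]]
  l <- obs$ligand_total_uM
  verdict <- function(specific, lin_rss, sat_rss, p, kd, why) {
    structure(list(specific = specific, linear_rss = lin_rss,
                   saturating_rss = sat_rss, p_value = p, kd_hat = kd,
                   criterion = why),
              class = "fa_specificity")
  }
  if (sd(y) < 1e-12 * max(abs(y), 1)) {
    return(verdict(FALSE, 0, 0, 1, NA_real_, "flat response"))
  }
  lin <- lm(y ~ l)
  lin_rss <- sum(lin$residuals^2)
  # saturating alternative on a rescaled response so the anisotropy range
  # check never bites for intensity data
  y0 <- (y - min(y)) / (max(y) - min(y)) * 0.3
  sat_series <- fa_series(
    tibble(ligand_total_uM = l, anisotropy = y0),
    protein_total = attr(series, "protein_total_uM") %||% 1
  )
  sat <- withCallingHandlers(
    tryCatch(fit_one_site(sat_series, deplete = deplete),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(sat) || !sat$converged) {
    return(verdict(FALSE, lin_rss, NA_real_, 1, NA_real_,
                   "saturating model did not converge"))
  }
  scale_back <- (max(y) - min(y)) / 0.3
  sat_rss <- sat$rss * scale_back^2
  if (lin_rss < 1e-12 * sum(y^2)) {
    return(verdict(FALSE, lin_rss, sat_rss, 1, sat$kd_hat,
                   "response is exactly linear"))
  }
  f_stat <- max((lin_rss - sat_rss) / 1, 0) / (sat_rss / (n - 3))
  p <- pf(f_stat, 1, n - 3, lower.tail = FALSE)
  kd_ok <- is.finite(sat$kd_hat) && sat$kd_hat <= max(l)
  specific <- (p < level) && kd_ok
  why <- if (specific) {
    sprintf("saturating model preferred (F-test p = %.3g, Kd within tested range)", p)
  } else if (!kd_ok) {
    "fitted Kd exceeds the largest tested ligand concentration"
  } else {
    sprintf("no significant curvature over a straight line (F-test p = %.3g)", p)
  }
  verdict(specific, lin_rss, sat_rss, p, sat$kd_hat, why)
}

#' @export
print.fa_fit <- function(x, ...) {
  cat(sprintf(
    "<fa_fit> Kd = %.4g +/- %.3g uM, r_free = %.4f, r_bound = %.4f\n",
    x$kd_hat, x$kd_se, x$r_free_hat, x$r_bound_hat
  ))
  cat(sprintf("rss = %.4g, n = %d, depletion = %s, saturation covered = %.0f%%\n",
              x$rss, x$n_obs, x$deplete, 100 * x$saturation_fraction))
  invisible(x)
}

#' @export
print.fa_specificity <- function(x, ...) {
  cat(sprintf("<fa_specificity> specific binding: %s\n", x$specific))
  cat(sprintf("  linear rss = %.4g, saturating rss = %.4g, p = %.3g\n",
              x$linear_rss, x$saturating_rss, x$p_value))
  cat(" ", x$criterion, "\n")
  invisible(x)
}
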