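#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a binding fit into a parameter table
#'
#' @param x A `binding_fit` from [fit_individual()] or [fit_global()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term` (`"Kd"` or
#'   `"dmax_<residue>"`), `estimate`, `std.error`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("Kd", paste0("dmax_", names(x$dmax_hat))),
    estimate = c(x$kd_hat, unname(x$dmax_hat)),
    std.error = c(x$kd_se, unname(x$dmax_se))
  )
}

#' One-row summary of a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `kd_uM`, `kd_se_uM`, `n_residues`, `n_obs`,
#'   `rss`, `sigma` (residual s.d.), `converged`, `applicability`,
#'   `se_method`.
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    kd_uM = x$kd_hat, kd_se_uM = x$kd_se,
    n_residues = length(x$dmax_hat), n_obs = x$n_obs, rss = x$rss,
    sigma = sqrt(x$rss / max(x$n_obs - x$n_par, 1)),
    converged = x$converged, applicability = x$applicability,
    se_method = x$se_method
  )
}

#' Tidy a fluorescence-anisotropy fit
#'
#' @param x An `fa_fit` from [fit_one_site()].
#' @param ... Unused.
#' @return A tibble with rows `Kd`, `r_free`, `r_bound`.
#' @method tidy fa_fit
#' @export
tidy.fa_fit <- function(x, ...) {
  tibble(
    term = c("Kd", "r_free", "r_bound"),
    estimate = c(x$kd_hat, x$r_free_hat, x$r_bound_hat),
    std.error = c(x$kd_se, x$r_free_se, x$r_bound_se)
  )
}

#' One-row summary of a fluorescence-anisotropy fit
#'
#' @param x An `fa_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the estimates, `rss`, `n_obs`,
#'   `converged`, `saturation_fraction`.
#' @method glance fa_fit
#' @export
glance.fa_fit <- function(x, ...) {
  tibble(
    kd_uM = x$kd_hat, kd_se_uM = x$kd_se,
    r_free = x$r_free_hat, r_bound = x$r_bound_hat,
    rss = x$rss, n_obs = x$n_obs, converged = x$converged,
    saturation_fraction = x$saturation_fraction
  )
}
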