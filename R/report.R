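#' Build an affinity record
#'
#' One measured dissociation constant: ligand, method, Kd and its error.
#' A `Kd` of `NA` marks a "not applicable" entry (a method that detected no
#' specific binding), which is legal in an affinity table but cannot enter a
#' fold ratio.
#'
#' @param ligand Ligand name.
#' @param method Measurement method: `"NMR"`, `"FA"` or `"ITC"`.
#' @param kd Dissociation constant, uM (> 0), or `NA` for not applicable.
#' @param kd_err Standard error of `kd`, uM (optional).
#' @param note Free-text annotation.
#' @return A one-row tibble with columns `ligand`, `method`, `kd_uM`,
#'   `kd_err_uM`, `note`.
#' @export
affinity_record <- function(ligand, method = c("NMR", "FA", "ITC"),
                            kd = NA_real_, kd_err = NA_real_, note = "") {
  method <- match.arg(method)
  if (!is.na(kd) && kd <= 0) abort("kd must be > 0 (or NA for n.a.)")
  tibble(ligand = ligand, method = method, kd_uM = as.numeric(kd),
         kd_err_uM = as.numeric(kd_err), note = note)
}

#' Fold ratio of two affinities
#'
#' `Kd(a) / Kd(b)` for two records obtained by the same method, with the
#' relative errors propagated in quadrature:
#' \eqn{\sigma_{ratio}/ratio = \sqrt{(\sigma_a/K_a)^2 + (\sigma_b/K_b)^2}}.
#'
#' @param a,b One-row affinity records ([affinity_record()]); the ratio is
#'   `a` over `b`.
#' @return A one-row tibble: `ratio`, `ratio_err`, `method`.
#' @examples
#' dsedg <- affinity_record("DSeDG", "ITC", 2800, 180)
#' sedg <- affinity_record("SeDG", "ITC", 93.1, 2.6)
#' fold_ratio(dsedg, sedg) # ~30-fold weaker
#' @export
fold_ratio <- function(a, b) {
  if (!identical(a$method, b$method)) {
    abort("fold_ratio needs records from the same method")
  }
  if (is.na(a$kd_uM) || is.na(b$kd_uM)) {
    abort("fold_ratio is undefined for a not-applicable (n.a.) Kd")
  }
  ratio <- a$kd_uM / b$kd_uM
  rel <- sqrt(sum(c(a$kd_err_uM / a$kd_uM, b$kd_err_uM / b$kd_uM)^2,
                  na.rm = TRUE))
  tibble(ratio = ratio, ratio_err = ratio * rel, method = a$method)
}

#' Affinity comparison table
#'
#' Arranges affinity records as a ligand-by-method grid with "n.a." for
#' methods that detected no specific binding, the customary layout for
#' cross-method Kd comparisons.
#'
#' @param records Affinity records row-bound together.
#' @return A tibble with one row per ligand and one formatted
#'   `Kd +/- err uM` column per method.
#' @export
affinity_table <- function(records) {
  records |>
    mutate(cell = ifelse(
      is.na(.data$kd_uM), "n.a.",
      ifelse(is.na(.data$kd_err_uM),
             sprintf("%.4g", .data$kd_uM),
             sprintf("%.4g ± %.2g", .data$kd_uM, .data$kd_err_uM))
    )) |>
    select("ligand", "method", "cell") |>
    tidyr::pivot_wider(names_from = "method", values_from = "cell",
                       values_fill = "n.a.")
}

# allowed keys per config section
.config_schema <- list(
  top = c("seed", "out_dir", "alpha", "titration", "fit", "fa", "traj"),
  titration = c("kd_uM", "protein_total_uM", "n_points", "max_fold_kd",
                "noise_H_ppm", "noise_N_ppm"),
  fit = c("mode", "n_top", "n_boot"),
  fa = c("kd_uM", "nonspecific", "protein_total_uM", "r_free", "r_bound",
         "noise_r", "n_points", "max_ligand_uM"),
  traj = c("mean_bound_dwell_ns", "mean_unbound_dwell_ns", "bound_level_A",
           "unbound_level_A", "level_noise_A", "dt_ns", "duration_ns",
           "threshold_low_A", "threshold_high_A", "min_dwell_ns",
           "censor_last")
)

.check_keys <- function(x, section) {
  unknown <- setdiff(names(x), .config_schema[[section]])
  if (length(unknown) > 0) {
    prefix <- if (section == "top") "" else paste0(section, "$")
    abort(paste0("unknown config key: ", prefix, unknown[1]))
  }
}

#' Run the synthetic demonstration pipeline from a config
#'
#' Executes simulate -> CSP mapping -> Kd fit (and optionally a
#' fluorescence-anisotropy analysis and a residence-time analysis) from a
#' single structured config, writing TSV/JSON outputs when `out_dir` is set.
#' One root `seed` drives all modules (derived per-module seeds are fixed
#' offsets of it), so identical configs give identical numeric output. The
#' returned report embeds the config hash, seed and package version.
#'
#' @param config A named list, or a path to a YAML/JSON file. Sections:
#'   `titration` (planted Kd, concentrations, noise), `fit` (mode, panel
#'   size, bootstrap), `fa`, `traj`; top-level `seed`, `alpha`, `out_dir`.
#'   Unknown keys are rejected by name.
#' @return A `titrbind_report` list: `classification`, `fit`, `fa`,
#'   `traj`, plus `seed`, `config_hash`, `package_version`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  .check_keys(config, "top")
  for (sec in c("titration", "fit", "fa", "traj")) {
    if (!is.null(config[[sec]])) .check_keys(config[[sec]], sec)
  }
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.14
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  config_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  report <- list(seed = seed, config_hash = config_hash,
                 package_version = as.character(utils::packageVersion("titrbind")))

  tc <- config$titration %||% list()
  kd <- tc$kd_uM %||% 123
  pt <- tc$protein_total_uM %||% 270
  series <- design_ligand_series(pt, kd, n_points = tc$n_points %||% 12,
                                 max_fold_kd = tc$max_fold_kd %||% 10)
  ds <- simulate_titration(
    galectin_demo_residues(), kd = kd, protein_total = pt,
    ligand_points = series,
    noise_H = tc$noise_H_ppm %||% 0.002, noise_N = tc$noise_N_ppm %||% 0.02,
    seed = seed
  )
  profiles <- csp_profiles(ds, alpha = alpha)
  classification <- classify_perturbed(profiles)
  report$classification <- classification

  fc <- config$fit %||% list()
  mode <- fc$mode %||% "global"
  panel <- top_perturbed_residues(profiles, n = fc$n_top %||% 9)
  fit <- if (identical(mode, "global")) {
    fit_global(profiles, residues = panel)
  } else {
    fit_individual(profiles, residue = panel[1])
  }
  if (!is.null(fc$n_boot) && fc$n_boot > 0) {
    fit <- estimate_uncertainty(fit, "bootstrap", n_boot = fc$n_boot,
                                seed = seed + 1L)
  }
  report$fit <- fit

  if (!is.null(config$fa)) {
    fa <- config$fa
    fa_kd <- if (isTRUE(fa$nonspecific)) Inf else fa$kd_uM %||% 35.2
    fa_pts <- if (is.finite(fa_kd)) NULL else {
      c(0, exp(seq(log(1), log(fa$max_ligand_uM %||% 800),
                   length.out = (fa$n_points %||% 12) - 1L)))
    }
    fa_data <- simulate_fa_titration(
      true_kd = fa_kd, protein_total = fa$protein_total_uM %||% 3,
      r_free = fa$r_free %||% 0.10, r_bound = fa$r_bound %||% 0.20,
      ligand_points = fa_pts, noise_r = fa$noise_r %||% 0.002,
      seed = seed + 2L
    )
    report$fa <- list(
      verdict = test_specific_binding(fa_data),
      fit = if (is.finite(fa_kd)) fit_one_site(fa_data) else NULL
    )
  }

  if (!is.null(config$traj)) {
    tj <- config$traj
    trace <- simulate_distance_trace(
      mean_bound_dwell = tj$mean_bound_dwell_ns %||% 730,
      mean_unbound_dwell = tj$mean_unbound_dwell_ns %||% 50,
      bound_level = tj$bound_level_A %||% 5,
      unbound_level = tj$unbound_level_A %||% 30,
      level_noise = tj$level_noise_A %||% 1,
      dt = tj$dt_ns %||% 0.1,
      duration = tj$duration_ns %||% 20000,
      seed = seed + 3L
    )
    segs <- segment_bound_states(
      trace, threshold_low = tj$threshold_low_A %||% 10,
      threshold_high = tj$threshold_high_A %||% 20,
      min_dwell = tj$min_dwell_ns %||% 1
    )
    report$traj <- residence_stats(segs,
                                   censor_last = tj$censor_last %||% TRUE)
  }

  if (!is.null(out_dir)) {
    readr::write_tsv(classification, file.path(out_dir, "csp_classification.tsv"))
    jsonlite::write_json(
      list(
        seed = seed, config_hash = config_hash,
        package_version = report$package_version,
        kd_uM = fit$kd_hat, kd_se_uM = fit$kd_se,
        dmax_ppm = as.list(fit$dmax_hat), rss = fit$rss,
        applicability = fit$applicability, converged = fit$converged
      ),
      file.path(out_dir, "binding_fit.json"),
      auto_unbox = TRUE, digits = NA
    )
    if (!is.null(report$traj)) {
      readr::write_tsv(report$traj, file.path(out_dir, "traj_stats.tsv"))
    }
  }
  structure(report, class = "titrbind_report")
}

#' @export
print.titrbind_report <- function(x, ...) {
  cat(sprintf("<titrbind_report> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  print(x$fit)
  cat(sprintf("classified residues: %d (%d strong, %d intermediate)\n",
              nrow(x$classification),
              sum(x$classification$class == "strong"),
              sum(x$classification$class == "intermediate")))
  if (!is.null(x$fa)) print(x$fa$verdict)
  if (!is.null(x$traj)) {
    cat(sprintf("residence time: mean %.1f ns over %d events\n",
                x$traj$mean_ns, x$traj$n_events))
  }
  invisible(x)
}
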