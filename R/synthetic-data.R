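#' Design a ligand concentration series
#'
#' Zero (the apo reference) followed by a geometric ladder from a quarter of
#' the anticipated `Kd` up to `max_fold_kd` times it, which places points on
#' both sides of the inflection of the binding curve.
#'
#' @param protein_total Total protein concentration, uM (recorded for
#'   context; the ladder itself depends only on the Kd guess).
#' @param kd_guess Anticipated dissociation constant, uM.
#' @param n_points Total number of points including the apo reference
#'   (>= 4).
#' @param max_fold_kd Upper end of the ladder as a multiple of `kd_guess`.
#' @return Numeric vector of `n_points` ligand concentrations in uM,
#'   starting at 0.
#' @examples
#' design_ligand_series(270, 100, n_points = 4, max_fold_kd = 10)
#' @export
design_ligand_series <- function(protein_total, kd_guess, n_points = 12,
                                 max_fold_kd = 10) {
  if (n_points < 4) abort("n_points must be >= 4")
  if (kd_guess <= 0 || max_fold_kd <= 0) {
    abort("kd_guess and max_fold_kd must be > 0")
  }
  lo <- kd_guess / 4
  hi <- max_fold_kd * kd_guess
  c(0, exp(seq(log(lo), log(hi), length.out = n_points - 1L)))
}

#' Residue table for a galectin-like demonstration protein
#'
#' A 143-residue synthetic protein (numbered 108-250, the span of the hGal-3
#' carbohydrate recognition domain) with plausible free amide shifts and
#' planted bound-state shift offsets that mimic a canonical S-face sugar
#' binding site: large offsets at residues 158 and 174, intermediate at 175
#' and 176, small at 159 and 160, a moderately shifted block 182-190, and a
#' remote F-face reporter at 222. All other residues have zero offset. The
#' table is deterministic (free shifts come from a fixed internal seed).
#'
#' @return A tibble with columns `residue_id`, `residue_name`, `dH_free`,
#'   `dN_free`, `dH_offset`, `dN_offset` suitable for
#'   [simulate_titration()].
#' @export
galectin_demo_residues <- function() {
  ids <- 108:250
  n <- length(ids)
  base <- withr::with_seed(20220224, {
    tibble(
      residue_id = ids,
      residue_name = sample(c("ALA", "GLY", "LEU", "SER", "THR", "VAL",
                              "ASN", "HIS", "LYS", "PHE", "ARG", "GLU"),
                            n, replace = TRUE),
      dH_free = round(runif(n, 6.8, 9.6), 3),
      dN_free = round(runif(n, 104, 130), 2),
      dH_offset = 0, dN_offset = 0
    )
  })
  # canonical identities of the landmark residues
  known <- c("158" = "HIS", "159" = "PHE", "160" = "ASN", "162" = "ARG",
             "174" = "ASN", "175" = "THR", "176" = "LYS", "181" = "TRP",
             "183" = "ARG", "184" = "GLU", "185" = "GLU", "186" = "ARG",
             "187" = "GLN", "222" = "ASN")
  hit <- match(as.character(base$residue_id), names(known))
  base$residue_name[!is.na(hit)] <- known[hit[!is.na(hit)]]
  plant <- function(df, ids, dh, dn) {
    i <- df$residue_id %in% ids
    df$dH_offset[i] <- dh
    df$dN_offset[i] <- dn
    df
  }
  base |>
    plant(c(158, 174), 0.14, 0.9) |>      # mostly perturbed, binding subsite
    plant(c(175, 176), 0.08, 0.55) |>     # intermediate
    plant(c(159, 160), 0.035, 0.25) |>    # minor
    plant(182:190, 0.06, 0.4) |>          # distal-subsite block
    plant(222, 0.05, 0.35)                # remote reporter
}

#' Simulate a fast-exchange HSQC titration
#'
#' Generates a full titration dataset under the fast-exchange model: at each
#' point the bound fraction follows the exact 1:1 depletion isotherm
#' ([fraction_bound()]) and each residue's observed peak is
#' `free shift + fraction_bound * bound-state offset` plus independent
#' Gaussian peak-position noise. The seed fully determines the output.
#'
#' @param residues Tibble with columns `residue_id`, `dH_free`, `dN_free`,
#'   `dH_offset`, `dN_offset` (and optionally `residue_name`); see
#'   [galectin_demo_residues()].
#' @param kd Planted dissociation constant, uM.
#' @param protein_total Total protein concentration, uM (default 270, a
#'   typical HSQC sample).
#' @param ligand_points Ligand concentrations in uM, starting at 0; default
#'   a 12-point series to 10x `kd` from [design_ligand_series()].
#' @param noise_H,noise_N Gaussian peak-position noise, ppm s.d. (defaults
#'   0.002 and 0.02, typical HSQC digital resolution).
#' @param seed Integer seed.
#' @param metadata Metadata list stored on the dataset.
#' @return A `titration_data` tibble.
#' @examples
#' ds <- simulate_titration(galectin_demo_residues(), kd = 123, seed = 1)
#' @export
simulate_titration <- function(residues, kd, protein_total = 270,
                               ligand_points = NULL,
                               noise_H = 0.002, noise_N = 0.02,
                               seed = 1, metadata = list()) {
  if (noise_H < 0 || noise_N < 0) abort("noise must be >= 0")
  if (kd <= 0) abort("kd must be > 0")
  residues <- as_tibble(residues)
  if (!"residue_name" %in% names(residues)) residues$residue_name <- ""
  ligand_points <- ligand_points %||%
    design_ligand_series(protein_total, kd, n_points = 12, max_fold_kd = 10)
  if (ligand_points[1] != 0) {
    abort("ligand_points must start at 0 (apo reference)")
  }
  n_res <- nrow(residues)
  n_pts <- length(ligand_points)
  fb <- fraction_bound(protein_total, ligand_points, kd)
  long <- withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      point_index = seq_len(n_pts),
      residues
    )
    grid$ligand_total_uM <- ligand_points[grid$point_index]
    grid$fb <- fb[grid$point_index]
    grid |>
      mutate(
        protein_total_uM = protein_total,
        delta_H_ppm = .data$dH_free + .data$fb * .data$dH_offset +
          rnorm(n_pts * n_res, 0, noise_H),
        delta_N_ppm = .data$dN_free + .data$fb * .data$dN_offset +
          rnorm(n_pts * n_res, 0, noise_N),
        quality = "ok"
      ) |>
      select("point_index", "protein_total_uM", "ligand_total_uM",
             "residue_id", "residue_name", "delta_H_ppm", "delta_N_ppm",
             "quality")
  })
  as_titration_data(long, metadata = c(
    metadata,
    list(true_kd_uM = as.character(kd), seed = as.character(seed))
  ))
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Specific mode (finite `true_kd`): anisotropy follows the one-site curve
#' with ligand depletion via the exact quadratic, plus Gaussian noise.
#' Nonspecific mode (`true_kd = Inf`): flat-plus-noise anisotropy with a
#' linearly decreasing intensity, the signature of absent specific binding.
#'
#' @param true_kd Planted dissociation constant in uM, or `Inf` for the
#'   nonspecific mode.
#' @param protein_total Total protein concentration, uM (default 3, roughly
#'   0.05 mg/mL of a ~16 kDa domain).
#' @param r_free,r_bound Anisotropy of the free and bound protein.
#' @param ligand_points Ligand concentrations, uM; default 12 points from
#'   0.1x to 30x `true_kd` (nonspecific mode requires an explicit series).
#' @param noise_r Gaussian anisotropy noise s.d. (default 0.002).
#' @param intensity0 Intensity at zero ligand (a.u.).
#' @param intensity_slope Linear intensity change per uM ligand (negative
#'   for a decrease); applied in both modes.
#' @param noise_I Gaussian intensity noise s.d. (a.u.).
#' @param seed Integer seed.
#' @return An [fa_series()] tibble (columns `ligand_total_uM`, `anisotropy`,
#'   `intensity`, `A_ex`, `A_em`).
#' @export
simulate_fa_titration <- function(true_kd, protein_total = 3,
                                  r_free = 0.10, r_bound = 0.20,
                                  ligand_points = NULL, noise_r = 0.002,
                                  intensity0 = 1000, intensity_slope = 0,
                                  noise_I = 0, seed = 1) {
  if (noise_r < 0 || noise_I < 0) abort("noise must be >= 0")
  if (is.null(ligand_points)) {
    if (!is.finite(true_kd)) {
      abort("nonspecific mode (true_kd = Inf) needs explicit ligand_points")
    }
    ligand_points <- c(0, exp(seq(log(0.1 * true_kd), log(30 * true_kd),
                                  length.out = 11)))
  }
  n <- length(ligand_points)
  r_true <- if (is.finite(true_kd)) {
    r_free + (r_bound - r_free) *
      fraction_bound(protein_total, ligand_points, true_kd)
  } else {
    rep(r_free, n)
  }
  out <- withr::with_seed(seed, {
    tibble(
      ligand_total_uM = ligand_points,
      anisotropy = r_true + rnorm(n, 0, noise_r),
      intensity = intensity0 + intensity_slope * ligand_points +
        rnorm(n, 0, noise_I),
      A_ex = 0, A_em = 0
    )
  })
  fa_series(out, protein_total = protein_total)
}

#' Simulate a two-state telegraph distance trace
#'
#' A protein-ligand distance time series that alternates between a bound and
#' an unbound level with independent exponentially distributed dwell times,
#' starting in the bound state (a soaked/complexed starting structure), plus
#' Gaussian level noise at every sample. The seed fully determines the
#' trace.
#'
#' @param mean_bound_dwell,mean_unbound_dwell Mean dwell times, ns (> 0).
#' @param bound_level,unbound_level Distance levels, Angstrom
#'   (`bound_level < unbound_level`).
#' @param level_noise Gaussian noise s.d. on the distance, Angstrom.
#' @param dt Sampling interval, ns; must resolve the dwells
#'   (`dt < min(mean dwell)/10`).
#' @param duration Trace length, ns. Below 5 expected bound/unbound cycles a
#'   `short_trace` flag is set in the attributes.
#' @param seed Integer seed.
#' @return A `distance_trace` tibble with columns `t_ns`, `distance_A` and
#'   attributes `dt_ns`, `short_trace`.
#' @export
simulate_distance_trace <- function(mean_bound_dwell, mean_unbound_dwell,
                                    bound_level = 5, unbound_level = 30,
                                    level_noise = 1, dt = 0.1,
                                    duration = 10000, seed = 1) {
  if (mean_bound_dwell <= 0 || mean_unbound_dwell <= 0) {
    abort("dwell means must be > 0")
  }
  if (bound_level >= unbound_level) {
    abort("bound_level must be below unbound_level")
  }
  if (dt >= min(mean_bound_dwell, mean_unbound_dwell) / 10) {
    abort("dt must be < min(mean dwell)/10 to resolve the dwells")
  }
  short <- duration < 5 * (mean_bound_dwell + mean_unbound_dwell)
  if (short) {
    warn("trace shorter than 5 expected bound/unbound cycles")
  }
  out <- withr::with_seed(seed, {
    cum <- 0
    dwells <- numeric(0)
    means <- c(mean_bound_dwell, mean_unbound_dwell)
    state <- 1L # start bound
    # strictly alternating draws keep the stream stable under the seed
    while (cum < duration) {
      d <- rexp(1, rate = 1 / means[state])
      dwells <- c(dwells, d)
      cum <- cum + d
      state <- 3L - state
    }
    t <- seq(0, duration - dt, by = dt)
    seg <- findInterval(t, cumsum(dwells)) # 0-based segment index
    bound <- seg %% 2L == 0L
    level <- ifelse(bound, bound_level, unbound_level)
    tibble(t_ns = t, distance_A = level + rnorm(length(t), 0, level_noise))
  })
  structure(out, dt_ns = dt, short_trace = short,
            class = c("distance_trace", class(tibble())))
}
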