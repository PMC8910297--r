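# titrbind

Quantitative 1:1 protein–ligand binding analysis from solution titrations
and simulation output, built for the kind of study where a lectin (such as
the human galectin-3 carbohydrate recognition domain) is titrated with
carbohydrate ligands and the affinity is cross-checked between NMR,
fluorescence anisotropy and simulation.

The package covers four stages, each usable on its own:

- **Chemical-shift perturbation (CSP) mapping.** From ¹⁵N-¹H HSQC peak
  tables across a titration, per-residue combined shift distances
  *d* = √(½[Δδ²_H + (α·Δδ_N)²]) with α = 0.14, ranked and classified
  (strong / intermediate / minor / unperturbed) to map the binding site.
- **K_d fitting with ligand depletion.** The exact 1:1 isotherm
  Δd = Δd_max·[(P_t+L_t+K_d) − √((P_t+L_t+K_d)² − 4P_tL_t)]/(2P_t),
  fitted per residue or globally with one shared K_d and per-residue
  saturation amplitudes; covariance and bootstrap uncertainties; a flag
  when the estimate approaches the ~1 µM–10 mM applicability window of the
  HSQC approach.
- **Fluorescence anisotropy.** Inner-filter and dilution corrections, a
  one-site specific-binding fit (with or without depletion), and an F-test
  that turns "the response follows a straight line" into a reproducible
  no-specific-binding verdict.
- **Trajectory post-processing.** Hysteresis segmentation of
  protein–ligand distance traces into bound-state residence times, plus
  signed dihedrals (IUPAC convention) and circular means.

Seed-deterministic generators (`simulate_titration()`,
`simulate_fa_titration()`, `simulate_distance_trace()`) produce synthetic
data with planted ground truth for every stage, so the whole pipeline is
testable without any experimental download.

Everything is tidyverse-native: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

A small bundled titration (14 residues, 6 points, planted K_d = 123 µM,
P_t = 270 µM) ships as plain CSV:

```r
library(titrbind)
library(dplyr)

path <- system.file("extdata", "sedg_demo_titration.csv", package = "titrbind")
ds <- read_peak_table(path, "long_csv")

profiles <- csp_profiles(ds, alpha = 0.14)
classify_perturbed(profiles) |> filter(class %in% c("strong", "intermediate"))
#> # A tibble: 2 × 5
#>   residue_id residue_name d_final class         rank
#>        <int> <chr>          <dbl> <fct>        <int>
#> 1        158 HIS            0.119 intermediate     1
#> 2        174 ASN            0.118 intermediate     2

fit <- fit_global(profiles, residues = top_perturbed_residues(profiles, 9))
fit
#> <binding_fit:global> Kd = 128.4 +/- 10.5 uM (covariance SE), 9 residue(s), 45 obs
#> rss = 0.0001462, converged = TRUE, applicability = ok
```

The two most-perturbed residues (His158, Asn174) flank the sugar-binding
subsite of the demo fixture, and the nine-residue global fit recovers the
planted 123 µM affinity within its standard error. `autoplot(fit)` draws
the per-residue isotherms; `tidy(fit)` returns the K_d and per-residue
Δd_max estimates with standard errors.

Cross-method affinity comparisons use `affinity_record()` /
`fold_ratio()`:

```r
fold_ratio(affinity_record("DSeDG", "ITC", 2800, 180),
           affinity_record("SeDG",  "ITC", 93.1, 2.6))
#> # A tibble: 1 × 3
#>   ratio ratio_err method
#>   <dbl>     <dbl> <chr>
#> 1  30.1      2.11 ITC
```

`run_pipeline()` drives simulate → CSP → fit → (FA, trajectory) from one
YAML/JSON config with a single root seed and writes TSV/JSON reports.

## Vignette

`vignettes/binding-analysis.Rmd` documents the models and their
assumptions, the default parameters and why they were chosen, the
numerical details of the fits and the segmentation, and what passing the
planted-truth test suite does and does not demonstrate about real data.
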