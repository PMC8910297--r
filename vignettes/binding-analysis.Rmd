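---
title: "Quantifying protein–ligand binding from titrations and distance traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–ligand binding from titrations and distance traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(titrbind)
library(dplyr)
```

titrbind analyzes 1:1 protein–ligand binding from three complementary kinds
of raw data: ¹⁵N-¹H HSQC titration peak tables, tryptophan
fluorescence-anisotropy titrations, and distance traces from
molecular-dynamics style simulations. This vignette explains the models the
package fits, the assumptions behind them, the defaults it chooses where
practice varies, and what its synthetic-data generators do and do not
emulate.

## Chemical-shift perturbation mapping

In the fast-exchange regime — ligand on/off kinetics fast relative to the
chemical-shift timescale, the situation for µM–mM binders — each amide cross
peak sits at the population-weighted average of its free and bound
positions. Binding therefore moves peaks continuously along the titration,
and the per-residue displacement maps the binding site.

Proton and nitrogen shifts live on different scales, so the package
collapses them into the standard combined distance

$$d = \sqrt{\tfrac{1}{2}\left[\Delta\delta_H^2 +
      (\alpha\,\Delta\delta_N)^2\right]}$$

with a single global scaling factor $\alpha = 0.14$, the conventional ratio
of amide ¹H to ¹⁵N shift dispersions. We deliberately use one $\alpha$ for
all residue types: per-type refinements (e.g. a smaller factor for glycine)
change little at the classification level and introduce one more arbitrary
choice. `csp_profiles()` computes $d$ per residue and titration point
against the mandatory apo reference; peaks flagged `overlapped` or
`missing` yield gaps rather than imputed values, because an unobserved peak
carries no evidence.

`classify_perturbed()` ranks residues by their final-point $d$ — the point
with the largest bound population and the best contrast — and classifies
them with a mean-plus-$k$-sigma ladder ($k = 2$: strong, $k = 1$:
intermediate, $k = 0$: minor). The literature describes perturbation tiers
qualitatively ("mostly perturbed", "intermediate", "minor"), with no numeric
cutoffs to inherit, so a scale-free rule was chosen: it is invariant under a
common rescaling of all distances and under residue reordering. Absolute
ppm cutoffs are available through `method = "fixed_cutoffs"` for users who
prefer field conventions like 0.05/0.1 ppm.

## Dissociation constants from the exact depletion isotherm

At protein concentrations suitable for HSQC detection (hundreds of µM) the
free-ligand approximation fails badly, so the package always fits the exact
1:1 isotherm

$$\Delta d = \Delta d_{max}\,
  \frac{(P_t+L_t+K_d) - \sqrt{(P_t+L_t+K_d)^2 - 4P_tL_t}}{2P_t},$$

with total concentrations $P_t$, $L_t$ in µM. Numerically the root is
evaluated in the rationalized form $2P_tL_t/(S+\sqrt{S^2-4P_tL_t})$,
$S = P_t+L_t+K_d$, which is stable when the discriminant is small relative
to $S^2$ (tight binding near stoichiometric equivalence). The expression
depends only on concentration ratios, a property the test suite checks
directly.

`fit_individual()` fits $(K_d, \Delta d_{max})$ to one residue;
`fit_global()` fits one shared $K_d$ with one $\Delta d_{max}$ per residue,
jointly over all observations with uniform weights. Per-residue amplitudes
are essential: residues report different bound-state shifts, and forcing a
common amplitude would bias the shared $K_d$. Observations enter the fit
only when the peak is usable (`ok`) and ligand is present.

Numerical choices: Levenberg–Marquardt least squares (`minpack.lm`),
relative tolerances $10^{-10}$ on parameters and $10^{-12}$ on the sum of
squares, at most 500 iterations, lower bounds $K_d > 0$,
$\Delta d_{max} \ge 0$. Initialization is scale-free — $K_d^{(0)}$ at the
median tested ligand concentration and $\Delta d_{max}^{(0)}$ at 1.2 times
the last observed shift change — so the same defaults work from µM to mM
affinities. Non-convergence is reported (`converged = FALSE`), never thrown.
A profile with no signal (all shifts zero) legitimately ends with
$\Delta d_{max} \approx 0$ and an unbounded $K_d$ uncertainty.

Two uncertainty estimators are provided, because "analyze the quality of
fit" admits more than one reading: the Gauss–Newton covariance at the
optimum (default, with a singularity flag), and residual-resampling
bootstrap (`estimate_uncertainty(..., "bootstrap")`), fully determined by
its seed. On well-conditioned synthetic data the two agree within tens of
percent; the test suite pins this at 30%.

HSQC titrations resolve affinities reliably only within roughly
1 µM < $K_d$ < 10 mM. Fits approaching either edge are flagged
(`near_tight_limit` below 2 µM, `near_weak_limit` above 5 mM — twice inside
each endpoint, a soft warning before the hard limit). The weak-binding
degradation the field observes is reproduced in the tests not by the $K_d$
magnitude itself — the isotherm is scale-invariant — but by the practical
ceiling on ligand concentration: when solubility truncates the series at
half of $K_d$, the relative uncertainty of a single-residue fit grows
several-fold relative to a titration that reaches 10× $K_d$.

## Fluorescence anisotropy

A tryptophan stacking against a bound sugar reports binding through its
anisotropy $r$. `fit_one_site()` fits $r_{free}$, $r_{bound}$ and $K_d$,
either with the hyperbolic bound fraction $L/(K_d+L)$ or with the same
exact depletion quadratic as the NMR case (`deplete = TRUE`, the default);
the two converge as $P_t/K_d \to 0$, and the test suite checks agreement at
ratio $10^{-3}$. A fit whose data cover less than 30% of the fitted
amplitude is flagged as unsaturated but still returned.

Supporting corrections are provided as separate composable steps:
`inner_filter_correct()` applies the half-path absorbance correction
$F\cdot 10^{(A_{ex}+A_{em})/2}$ — the cited literature formula is the
standard half-geometry form, isolated in one function so an instrument-
specific variant can be substituted — and `dilution_correct()` rescales for
cumulative titrant volume.

The "no specific binding" verdict, visually a straight-line response, is
operationalized in `test_specific_binding()`: fit both a line (2
parameters) and the one-site curve (3 parameters), and call binding
specific only when the extra parameter survives an F-test at level 0.05
*and* the fitted $K_d$ lies within the tested concentration range. The
saturating alternative is fitted without depletion, since the test regime
is weak-to-absent binding at trace protein. Because the bounded one-site
curve cannot reproduce an arbitrary straight line exactly, the test is
slightly conservative; its empirical size under a linear null stays below
the nominal level in the 500-replicate suite check.

## Residence times and dihedral statistics

Simulated dissociation is tracked by a protein–ligand distance.
`segment_bound_states()` segments the trace with hysteresis (a Schmitt
trigger): enter bound below `threshold_low`, leave above `threshold_high`.
The dead band absorbs level noise that would make a single cutoff flicker;
runs shorter than `min_dwell` are merged into their neighbors, shortest
first. No community-standard cutoff exists for "bound", so both thresholds
are mandatory, explicit parameters; the defaults (5 and 10 Å) suit
center-of-mass separations. `residence_stats()` reports mean and median
dwell, event count and bound fraction; `censor_last = TRUE` drops a dwell
cut off by the end of the trace, a user decision because whether a
non-dissociating final interval should count is a judgment about the
simulation, not the estimator.

`dihedral()` returns signed torsions in the IUPAC convention (cis = 0°,
clockwise positive sighting down the central bond) in $(-180°, 180°]$;
collinear triples are an error, not a silent NaN. Published torsion values
of ±90° are consistent with either sign convention up to mirror symmetry,
so the convention is documented rather than inferred. `circular_mean()`
averages angles through the resultant vector, the only average that
respects wrap-around; a (near-)uniform sample has no defined mean direction
and errors out at resultant length $10^{-8}$.

## What the synthetic generators emulate — and what they do not

`simulate_titration()` produces peak tables under exactly the model the
fitters assume: depletion-isotherm populations, linear peak movement
between free and bound positions, independent Gaussian peak-position noise
($\sigma_H = 0.002$, $\sigma_N = 0.02$ ppm by default, typical HSQC digital
resolution at 500 MHz). The bundled `galectin_demo_residues()` fixture
plants a canonical galectin-like perturbation pattern across a 143-residue
CRD: strong shifts at the sugar-binding subsite (residues 158, 174),
intermediate (175, 176) and minor (159, 160) neighbors, a distal-subsite
block (182–190) and one remote reporter (222).

`simulate_fa_titration()` generates one-site anisotropy curves (specific
mode) or flat anisotropy with a linear intensity decrease (nonspecific
mode, `true_kd = Inf`). The default protein concentration is 3 µM — a
0.05 mg/mL solution of a ~16 kDa domain — since fluorescence assays run at
trace protein. `simulate_distance_trace()` draws alternating exponential
bound/unbound dwells starting bound (a complexed starting structure) with
Gaussian level noise.

Because generator and fitter share the same forward model, recovery tests
certify the estimation machinery, not the model's adequacy for real
spectra. Real data add what the generators omit: peak overlap and
assignment errors, exchange broadening near the fast/intermediate boundary,
correlated baseline drifts in anisotropy, photobleaching, and
multi-exponential or diffusive recrossing kinetics in trajectories. Passing
the planted-truth suite therefore shows correctness of the computation, not
robustness to every experimental pathology.

Problem sizes in the tests and the acceptance script were fixed up front
for sampling adequacy: 20 simulation seeds per recovery scenario (median
reported), 12-point titrations, and a 400 µs-scale telegraph trace giving
roughly 500 bound events, at which the standard error of the mean dwell is
about 4.5% of its value.

## Known limitations

Only 1:1 binding is modeled — no cooperativity, no multi-site or
competitive schemes, and no slow/intermediate-exchange lineshape analysis.
Peak tables must arrive assigned and picked; the package does no spectral
processing. The wide CSV dialect stores per-point concentrations in header
lines and optional quality columns, a package-defined layout documented in
`read_peak_table()`. Anisotropy is consumed as given (no G-factor
computation from polarized intensities). Trajectory input is a distance
time series, not a trajectory file: atom selection and distance extraction
belong to upstream tools.
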