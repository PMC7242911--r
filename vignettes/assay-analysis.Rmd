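---
title: "Models and methods: binding isotherms, water-flux kinetics and assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: binding isotherms, water-flux kinetics and assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquassay)
```

# Scope

`aquassay` implements the quantitative chain that links a membrane
protein's ligand binding to its physiological readouts: microscale
thermophoresis (MST) titrations fitted to a depletion-corrected binding
isotherm, inhibitor dose-response curves, stopped-flow liposome
shrinkage converted to osmotic and single-channel water permeabilities,
calcein-quench cell-volume kinetics, membrane-accumulation half-times,
tissue- and image-level summaries, and the statistics used to compare
the resulting estimates. The motivating system is aquaporin-4 (AQP4)
binding Ca²⁺-calmodulin (CaM), the interaction that drives AQP4 to the
astrocyte surface in CNS edema, but nothing in the code is specific to
that pair.

# The binding model and why depletion matters

A classical hyperbolic fit assumes the free ligand concentration equals
the total pipetted concentration. In an MST titration the labelled
receptor is held at `p_tot` (default 17 µM) while the ligand spans
0.4–160 µM; with a dissociation constant of tens of µM, a substantial
fraction of ligand at the low end of the titration is receptor-bound,
and ignoring that biases Kd upward. `free_ligand()` therefore solves the
1:1 mass balance exactly (the positive root of the quadratic) and
`binding_signal()` evaluates the isotherm at that free concentration;
`fit_binding()` composes the two and estimates (S1, S2, Kd) by nonlinear
least squares.

Numerical choices:

* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nlsLM`) with Kd
  bounded in (10⁻³, 10⁵) µM and a five-point multi-start over log-spaced
  Kd initial values. The bound and multi-start exist because the
  likelihood is nearly flat in Kd once Kd exceeds the largest titrated
  concentration: a single start can stall on that plateau. S1 and S2
  start from the signal at the lowest and highest concentration.
* **No-binding decision.** Controls (Ca²⁺ chelation, inhibitor
  saturation, binding-site mutants) should be declared "no binding"
  rather than be assigned a meaningless Kd. The criterion is an
  extra-sum-of-squares F-test of the 3-parameter isotherm against a
  constant model at α = 0.05, with a fit that runs into the upper Kd
  bound also declared negative. A flat series then fails to justify its
  two extra parameters.
* **Signal conventions.** Because S1 and S2 are free, the fit is
  invariant to affine rescaling of the signal axis, so raw Fnorm,
  ΔFnorm or baseline-shifted signals all yield the same Kd.
* **Replicates.** Replicate series are pooled into one global fit, which
  matches how replicate dilution series are conventionally plotted and
  fitted as a single curve; per-replicate fits can be had by filtering
  the table before fitting.

`extract_fnorm()` reduces an MST time trace to the Fnorm = F0/F1 ratio
of window means. With `f1_window = "auto"` a fixed-width window (default
1 s) slides over the post-heating region and the window maximising
|mean − F0 mean| / pooled SD is chosen, ties going to the earliest
window — the same signal-to-noise criterion instrument software applies.

# Dose-response and IC50

`fit_dose_response()` fits the four-parameter logistic on the log₁₀
concentration axis. IC50 is reported as `10^x0` (the curve midpoint) and
its standard error by the delta method, `ln(10)·IC50·se(x0)`. Flat data
— including the degenerate A1 = A2 case — are flagged non-converged via
the same F-test-vs-constant logic as the binding fit, since a midpoint
of a flat curve is undefined.

The default inhibitor design used in the tests is 12 log-spaced
concentrations spanning 50–5000 µM. A two-fold series over a ten-fold
range cannot contain 12 distinct points, so published descriptions of
such designs are ambiguous; the generator therefore takes an explicit
concentration vector and the package picks a bracketing log-spaced
default rather than guessing a dilution scheme.

# Stopped-flow shrinkage and permeabilities

Liposome shrinkage under a hyperosmotic step raises the fluorescence of
an encapsulated self-quenching dye. Proteoliposome preparations are
heterogeneous: a fraction of liposomes carries no protein, so the trace
is a sum of a fast (protein-mediated) and a slow (lipid-background)
exponential. `fit_double_exponential()` fits

F(t) = baseline + a_fast(1 − e^(−k_fast t)) + a_slow(1 − e^(−k_slow t))

and selects the larger rate constant, which tracks the protein-containing
population; the smaller one is insensitive to reconstitution efficiency.
If the two components are degenerate (rates within 20% or a component
under 2% of the total amplitude) the model falls back to a single
exponential and says so — fitting two exponentials to one-exponential
data otherwise returns arbitrary splits. A trace that has not completed
one selected time constant within the acquisition is flagged
non-converged, since its plateau (and hence its rate) is unidentified.

The rate converts to the osmotic permeability

Pf = k / ((S/V₀) · V_w · C_out)

with S/V₀ = 3/r for a sphere (the 100 nm extrusion filter sets
r = 50 nm, so S/V₀ = 6 × 10⁵ cm⁻¹), V_w = 18 cm³ mol⁻¹ and
C_out = 10⁻⁴ mol cm⁻³ (0.1 Osm): the denominator is 1080 and
Pf = k/1080 cm/s.

**Single-channel permeability.** Pu = Pf/SuD requires the channel
density SuD, derived from the lipid-to-protein ratio (LPR) and the area
per lipid (0.47 nm²). Two genuinely open conventions are exposed rather
than hidden:

* `lpr_basis`: reconstitution protocols usually quote LPR by **mass**
  (the default, requiring protein and lipid molecular weights); a
  **molar** basis is also supported.
* `oligomer`: 1 (default) counts each monomer as a channel, matching
  the monomer-based concentration bookkeeping used in the binding fit;
  4 treats a tetramer as one particle.
* Background subtraction: by default the protein-free control Pf is
  subtracted before dividing, so Pu reflects protein-mediated flux only;
  the unsubtracted variant is a flag away.

These conventions change SuD by up to ~8×, which is exactly why the
package reports which convention produced a given Pu instead of
committing silently to one.

# Calcein quenching, volume conversion, accumulation kinetics

`fit_quench()` fits a single-exponential decay to the post-injection
segment of a calcein trace; the default injection time of 5 s follows
the plate-reader protocol (5 s baseline read, injection, 50 s read), and
maximum-|derivative| detection is available when the injection time is
unlogged. Decay indistinguishable from a constant returns k = 0 with a
flag rather than a spurious rate. Since fluorescence is only
proportional to volume through a nonlinear self-quenching curve,
`volume_calibration()`/`to_volume()` apply a monotone standard curve
(anchored at 1 → 1, both signals normalized to the resting state);
both the raw and volume-converted rate can be reported because assay
conventions differ on which is "the" shrinkage rate constant.

`accumulation_halftime()` fits surface-accumulation time courses to
`1 − e^(−kt)` and reports t½ = ln 2/k; rate constants of 0.7702 and
0.1238 min⁻¹ correspond to half-times of 0.9 and 5.6 min, the scale of
difference the fit is meant to resolve between wild-type and
binding-deficient constructs.

# Tissue and imaging summaries

* Water content is `100(wet − dry)/wet`, scale-invariant in the weights.
  Whether rows are individual animals or pooled repeats is the caller's
  choice; `water_content_summary()` summarises whichever table it is
  given.
* Perivascular enrichment uses mean-of-ROI-means within image and class
  (weighting ROIs equally regardless of size), then the per-image
  peri/non-peri ratio, then the per-animal mean of image ratios.
  Group statistics belong at the animal level: the hierarchy stops
  image-rich animals from dominating.
* Positive-pixel counting sets the background threshold to the maximum
  pixel across antibody-control images — the smallest threshold at which
  every control pixel is negative — and counts strictly greater pixels,
  so a control image always scores zero.
* CAP metrics use smoothing-free discrete extremum detection with a
  minimum trough-to-peak prominence (default 5% of the post-artifact
  range) to skip noise wiggles; amplitude is the first qualifying
  negative deflection to the next peak, and area is the trapezoidal
  integral of the full-wave-rectified negative component.

# Statistics

* **Z-test on two estimates**: `Z = (X̄1 − X̄2)/√(σ1² + σ2²)`. The
  default tail is one-sided. This is a deliberate, logged choice: for
  binding constants of 29 ± 5.6 and 17 ± 3.1 µM the one-sided normal
  tail gives p = 0.030, and comparisons of a mutant against wild-type
  affinity are typically framed directionally. The two-sided test is one
  argument away.
* **Kruskal–Wallis** uses mid-ranks with the standard tie correction;
  p comes from the χ² approximation, plus an exact permutation p
  (enumeration of all n! assignments) when total n ≤ 8, where the χ²
  approximation is at its worst.
* **Conover–Iman post hoc**: pairwise t statistics on mean ranks with
  the pooled rank variance S², the (N−1−H)/(N−k) shrinkage and N−k
  degrees of freedom — the original technical-report parameterization,
  coded here because no installed package provides it. Singleton groups
  are flagged untestable.
* **Bonferroni t tests**: pairwise or versus-reference Welch t tests
  with `p_adj = min(1, m·p)`; the preceding one-way ANOVA p is reported
  alongside but does not gate the pairwise tests by default, since
  legends that list "ANOVA followed by corrected t tests" rarely state
  gating; a `gatekeep` flag enables it.

# What the generators emulate — and what they do not

Each generator is a deterministic function of its parameters and a
mandatory seed (seeds are required, not defaulted, precisely so that no
test can silently depend on global RNG state). The noise models are the
package's own choices, since assay write-ups rarely state one: additive
Gaussian noise on signals (MST, dose-response, stopped-flow, quench) and
multiplicative lognormal noise where positivity is physical
(wet weights around a 0.1 g tissue-piece scale, ROI intensities). The
stopped-flow generator averages `n_reads = 10` independent noisy
readings, reproducing the √10 noise reduction of instrument averaging.
ROI tables draw 4–9 images per animal and 3–10 ROIs per image and class,
the ranges typical of confocal quantification.

What passing tests on these data do **not** show: real MST traces carry
temperature-jump transients and photobleaching; real shrinkage traces
have mixing artifacts and light-scattering contributions; real
micrographs require segmentation before any ROI table exists; and
biological between-animal variance is not Gaussian-with-known-sd. The
generators validate the estimators' correctness on their stated models,
not robustness to every instrument artifact.

# Problem sizes and tolerances used in the test suite

The recovery and calibration checks use: 200 simulated 12-point
titrations at 5% amplitude noise for Kd (median within 10%), 100 flat
controls for the no-binding flag rate (≥ 95%), 3 replicate 12-point
dose-response series at 2% noise for IC50 (within 5%), 1% noise on
stopped-flow traces for the Pf chain (within 3%), and 10,000 null
simulations for type-I calibration of the rank and t tests (rejection in
[0.04, 0.06] at α = 0.05). These sizes give Monte-Carlo error comfortably
inside each tolerance while keeping the suite quick to run.

# Known limitations

* The shrinkage analysis is the conventional exponential-rate treatment,
  not a Kedem–Katchalsky volume-flux ODE; rates from strongly
  non-exponential traces will be approximations.
* Published single-channel permeabilities depend on the SuD convention;
  values computed here are comparable across conditions analysed with
  the same convention but not necessarily to literature values derived
  under another.
* The Conover–Iman p-values are unadjusted pairwise p's, as in the
  original procedure; apply a multiplicity correction on top if the
  study design calls for one.
* `positive_pixel_count()` operates on numeric matrices; reading
  instrument TIFFs is left to the caller (e.g. the `tiff` package), as
  bit-depth handling is instrument-specific.
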