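---
title: "Methods: isotope tracing, damage scoring and platinum quantitation in cddpflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope tracing, damage scoring and platinum quantitation in cddpflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cddpflux)
```

`cddpflux` implements the computational chain of an in vitro
cisplatin/oxidative-stress study in tumour cells: stable-isotope tracing of
central carbon metabolism, single-cell DNA-damage (γH2AX) scoring,
internal-standard ICP-MS platinum quantitation, and endpoint assay
arithmetic. Every input has a seeded synthetic generator with attached
ground truth, so the whole chain can be exercised and validated without
instrument data.

## Mass isotopomer distributions and natural-abundance correction

A metabolite with $n$ carbons measured under a $^{13}$C tracer yields
intensities at mass shifts $m{+}0 \dots m{+}n$. The mass isotopomer
distribution (MID) is the vector of molecular fractions
$f_0, \dots, f_n$, $\sum_k f_k = 1$. Observed intensities are contaminated
by naturally occurring heavy isotopes: a molecule carrying $k$ tracer
carbons is observed at shift $k + j$ with probability
$\binom{n-k}{j} p^j (1-p)^{n-k-j}$, where $p$ is the per-carbon heavy
probability ($p = 0.0107$ for $^{13}$C). Stacking these binomial columns
gives the lower-triangular correction matrix $M$
(`natural_abundance_matrix()`); the observed spectrum is
$y \propto M f$.

`correct_mid()` recovers $f$ by solving $\min_{x \ge 0} \lVert Mx - y
\rVert_2$ (non-negative least squares) and renormalizing. We solve the
constrained problem rather than inverting $M$ because plain inversion
yields small negative fractions at low signal; the constraint guarantees a
valid MID. The unit tests check the solver against a brute-force
enumeration of all heavy-atom placements for $n \le 6$ and verify that
convolve-then-correct round-trips random MIDs to $10^{-8}$.

Only carbon isotopes are corrected: at unit SRM resolution the
contributions of other elements' isotopes are unresolved, and $p$ is
configurable for sensitivity analysis. Tracer purity is assumed to be
100%; the observed-spectrum model accepts an impure tracer only through
the MIDs themselves.

Two summary quantities are exposed as distinct operations because the
conventional phrase "fractional incorporation" is ambiguous between them:

* `labeled_fraction()` — the labeled-molecule fraction
  $100(1 - f_0)$, the default reported quantity (isotopologue bar plots
  stack $m{+}0$ against $m{+}k$);
* `mean_enrichment()` — the per-carbon atom enrichment
  $100 \sum_k k f_k / n$.

Exposing both avoids guessing which reading a downstream analysis wants.

## Condition contrasts

`contrast_conditions()` compares two conditions per metabolite and
isotopologue index with a two-tailed two-sample Student's t test on
replicate fractions (pooled variance by default, matching the named test;
Welch is available behind `var_equal = FALSE`), flags $p < 0.05$, and also
emits labeled-fraction contrasts per metabolite. Zero-variance groups
follow explicit conventions instead of erroring: equal means give
$p = 1$, unequal means give $p = 0$, both flagged `degenerate`. No
multiple-testing correction is applied by default, matching the study
design the package mirrors; isotopologue dispersion is reported as the
standard error of the mean (the bar-plot convention), while plate
endpoints report standard deviations.

`tca_mid_shift()` is a convenience view on the TCA isotopologues that
report cycle turnover from uniformly labeled glucose — citrate
$m{+}2$ (first oxidative turn), $m{+}4$ (second turn) and $m{+}5$
(reductive carboxylation signature) by default.

## The tracing generator and the pyruvate dilution

`gen_isotopologue_dataset()` produces spectra as
$y = T \cdot M f \cdot \varepsilon$ with total pool $T = 10^6$ a.u. and
multiplicative lognormal noise $\varepsilon$ (mean 1, default CV 0.05).
A lognormal is used because SRM peak areas are positive with roughly
concentration-proportional error. Defaults describe a 3-hour
U-$^{13}$C$_6$-glucose labeling experiment in a highly glycolytic cell
line: pyruvate 90% labeled ($m{+}3$), hexose phosphates mostly $m{+}6$,
pentose phosphates ~45–50% labeled, α-ketoglutarate <20% labeled, citrate
dominated by $m{+}2$ with some $m{+}4$. The treated condition suppresses
labeled pyruvate/lactate flux and raises citrate $m{+}2$/$m{+}4$ and
pentose-phosphate label — the shunting signature the contrast machinery
is meant to detect.

Lactate is derived, not declared: cells are routinely cultured with excess
unlabeled pyruvate, and that media pool dilutes the glycolytic label on
its way into lactate. The generator models lactate's tracer MID as
$(1-d)\,f^{\text{pyr}} + d\,\delta_{m+0}$. The media pyruvate
concentration behind $d$ is not a measured quantity, so $d$ is a free
parameter; its default $d = 0.2778$ is chosen so that 90% labeled
pyruvate yields $0.7222 \times 90 \approx 65\%$ labeled lactate, the
canonical 90-vs-65 pattern for this experimental design. The mixture law
is exact at zero noise and is one of the package's property tests.

## Single-cell γH2AX scoring

`segment_nuclei()` follows the standard marker-based watershed recipe:
Gaussian smoothing (σ = 2 px), Otsu global threshold on the
range-normalized image, Euclidean distance transform, distance-maxima
markers with a minimum separation (default 8 px — set it near the
expected nucleus radius), marker propagation through the foreground mask,
and removal of regions under 50 px. A blank field returns an empty label
map rather than an error.

Positivity follows a control-derived rule: the threshold is the mean plus
one standard deviation of control cells' mean nuclear intensities
(`derive_threshold()`), and a cell is positive when its intensity is
*strictly greater* than the threshold (`classify_positive()`). The sample
(n−1) standard deviation is used — the conventional estimator on a cell
population. Two consequences are tested as invariants: the percent
positive is invariant under any affine intensity rescaling applied
jointly to control and treated cells, and a Gaussian control population
scored against its own threshold yields $1 - \Phi(1) \approx 15.9\%$
positives.

`detect_foci()` counts damage foci as local maxima inside nuclei: the
channel is lightly Gaussian-smoothed (σ = 1 px) to stabilize maxima
against pixel noise, candidates must attain the maximum of their
`min_dist`-radius neighbourhood (default 3 px), and are kept when they
rise at least `prominence` above the nucleus's median intensity. The
default prominence is 3× the MAD-based robust sd of the channel, keeping
the detector scale-free; counts are monotonically non-increasing in
prominence. Restorative deconvolution is out of scope: the synthetic
fixtures are generated without the blur that would require it, and
z-stacks are reduced with `max_project()` before detection.

The image generator places disk nuclei (disks, not ellipses, so the
ground-truth label map is unambiguous) by rejection sampling with a
3-px clearance and errors out — never silently truncates — if the field
cannot hold the requested count. Foci are symmetric 2-D Gaussians
(σ = 1.5 px, amplitude 60 a.u. over a 5 a.u. noise floor, i.e. peaks
exceed background by far more than 5 noise sd) placed jointly within
0.7 r of the nucleus center with a minimum mutual separation of 7 px so
that neighbouring peaks remain resolvable; the separation is relaxed
geometrically when a crowded constellation cannot be placed, so
generation always terminates.

## ICP-MS platinum calibration

Platinum is quantified against an iridium internal standard:
`signal_ratio()` forms Pt/Ir with the three monitored Pt masses
(194, 195, 196) summed by default (single-mass policies by flag).
`fit_calibration()` regresses ratio on nominal concentration by weighted
least squares with weights $1/x^2$ — $x$ the nominal standard
concentration, the industry convention — because a serial-dilution series
spanning 0.125–50 ppb has concentration-proportional noise, and inverse
square weighting equalizes *relative* error so the low standards are not
swamped. The intercept is estimated rather than forced through zero
(forced-zero by flag). `back_calculate()` inverts the line, flags
estimates below the lowest standard, and clips negative estimates to
0 ppb with a flag (blanks legitimately scatter around zero).
`dna_bound_fraction()` forms the percent of total intra-cellular platinum
that is DNA-bound, with optional per-sample normalization scales; under
the default generator (bound:total ratio with mean 0.06) the recovered
median sits below 10%.

Property tests check the exact round-trip at zero noise, scale
equivariance of the fit, and that the weighted estimator beats unweighted
least squares at the lowest standard under relative noise (500
simulations).

## Endpoint arithmetic

Clonogenic surviving fractions are plating-efficiency normalized:
$PE = \text{colonies}/\text{plated}$ in the control,
$SF = (\text{colonies}/\text{plated})/PE$, so SF(control) = 1 identically
and SF is invariant to the plated cell number. Senescence is the percent
of positive cells per high-power field averaged over fields; zero-cell
fields are dropped with a warning. Redox ratios (NADH/NAD⁺, NADPH/NADP⁺)
are element-wise over paired replicates. `normalize_to_control()`
optionally divides by a cell-number surrogate (Hoechst DNA signal) before
expressing condition means relative to control. All condition-vs-control
testing routes through the same `ttest_two_tailed()` described above.

## Pipeline, determinism and problem sizes

`run_pipeline()` executes generate → isotope → imaging → ptquant → assays
from a single configuration (R list or YAML via `read_run_config()`,
which rejects unknown keys by name), persists every intermediate as tidy
TSV/CSV, multi-page TIFF (DAPI page first; 16-bit with a fixed
65 535 a.u. full scale) and JSON ground-truth sidecars, and reports
recovery metrics (`recovery_metrics()`: bias, MAE, and flag
coverage/false-flag rates when significance calls are compared to the
generated truth). All randomness flows from the single top-level seed;
sub-generator seeds are derived from it by fixed offsets, and generators
use an isolated RNG scope so they never perturb the caller's RNG state.
Two runs with the same configuration are identical, including the
persisted bytes.

The validation suite runs at deliberately modest problem sizes — 10 000
simulated null datasets for test calibration, 1 000 random MIDs per
carbon-count/abundance combination for the correction oracle, 200
metabolite pairs for labeled-fraction recovery, 20 synthetic fields for
segmentation and 200 nuclei for foci recovery — sizes at which the
binomial/Monte-Carlo error of each check is several times smaller than
the tolerance it is held to.

## What the synthetic data do and do not show

The generators reproduce the *statistical structure* of the study's
inputs: MID mixing and natural-abundance contamination, multiplicative
intensity noise, condition-dependent nuclear intensity and foci counts,
and heteroscedastic calibration noise. They do not emulate
chromatographic peak shape or integration error, ionization or detector
physics, optical blur requiring deconvolution, nucleus shape variation
beyond disks, or spatial correlation of microscope noise. Passing tests
therefore demonstrate that the analysis chain is mathematically correct
and well-calibrated under its stated noise models — not that those models
capture every artifact of real instruments. Known limitations: the
correction matrix addresses carbon only, so data from high-resolution
instruments resolving other-element isotopes need upstream handling; the
watershed recipe assumes roughly convex nuclei; and the pooled t test
inherits its usual sensitivity to unequal variances (use the Welch flag
when that matters).
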