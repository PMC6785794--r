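---
title: "Bone marrow dosimetry for 177Lu-DOTATATE: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone marrow dosimetry for 177Lu-DOTATATE: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowdose)
```

This vignette is the package's account of its science: the dose model and
its assumptions, the tunable parameters and their defaults, what the
synthetic generators emulate (and what they do not), the numerical choices
made where the method description left room, and the known limitations.

## The dose model

Red marrow cannot be segmented on planar scintigraphy, so the method uses
the *low-uptake compartment* — the whole body minus the threshold-defined
high-uptake organs (liver, spleen, kidneys, tumours) — as the marrow
surrogate. The marrow absorbed dose per treatment fraction is

$$D_{BM} = \tilde C_{BM}\,\phi_{BM\leftarrow BM}\,\Delta
  \;+\; \tilde A_{low}\,S_{BM\leftarrow low}
  \;+\; \tilde A_{high}\,S_{BM\leftarrow high},$$

with $\tilde C_{BM} = k\,\tilde A_{low}/m_{low}$. The first term is the
electron self-dose: $\Delta = 147$ keV of locally absorbed energy per
$^{177}$Lu decay, absorbed fraction $\phi_{BM\leftarrow BM} = 1$. With
$\tilde C$ in MBq·h/g, the unit chain
$3.6\times10^9$ decays/(MBq·h) $\times\,1.602\times10^{-16}$ J/keV
$\times\,10^3$ g/kg gives 0.08478 Gy per MBq·h/g at 147 keV
(`self_dose_coefficient()`); the tests verify this against an independent
hand conversion. The cross terms use photon-only S factors, organ-mass
weighted per compartment and per sex.

The scale factor $k$ distinguishes the methods. The *planar* method uses
the fixed population ratio $k = 1.8$ between marrow and low-compartment
activity concentration. The *hybrid* methods measure $k$ per patient as
the ratio of a vertebral-body SPECT concentration at 24 h to the fitted
low-compartment concentration curve evaluated at 24 h. Four reference
schemes are provided: L4-SPECT (single vertebra, fallback L4→L5→L3→L2
when metastatic or out of the field of view), and the medians over all
visible, lumbar, or thoracic vertebrae (V-, L-, T-SPECT). Metastatic
vertebrae are excluded only from the L4 fallback chain; the median
schemes keep them and rely on the median's robustness. At $k = 1.8$ the
hybrid equation reduces to the planar one exactly, which the acceptance
tests check to machine precision over random inputs.

Doses are reported both in Gy and normalised to 7.4 GBq administered
activity (the normalisation is linear). Fraction doses accumulate within
a method; the fraction-2 dose-response analysis uses the cumulative dose.

## Activity quantification

Compartment activities come from the conjugate-view formula applied to
paired anterior/posterior images,

$$A = \frac{\sqrt{R_{ant} R_{post}}}{s}\;
      e^{\mu_{eff} d/2}\;\frac{\mu_{eff} t/2}{\sinh(\mu_{eff} t/2)},$$

with sensitivity $s$ and effective attenuation coefficient $\mu_{eff}$
fitted by ordinary least squares in log space from a phantom depth series
(`fit_attenuation_sensitivity()`); the log-space fit matches the
exponential model exactly and is deterministic, and a positive fitted
slope is clamped to $\mu_{eff} = 0$ with a warning. $\mu_{eff}$ is a
broad-beam value: no scatter correction is applied anywhere, so scatter
is absorbed empirically into the calibration. The body thickness $d$ is a
single per-patient abdominal value; the source thickness defaults to the
general organ thickness $t = 8$ cm. The formula is exact for a uniform
source slab centred in a uniform attenuator — precisely the geometry the
synthetic phantom constructs, which is why noiseless recovery to
$10^{-6}$ relative error is a meaningful test rather than a tautology.

Segmentation operates on the geometric mean of the anterior and
mirrored-posterior images (mirroring about the vertical axis, since the
two detectors face each other). The whole-body outline is taken on a
Gaussian-smoothed copy (default sigma 2 px) at a fraction
`wb_threshold_frac = 0.02` of the smoothed maximum (largest connected
component, closed, hole-filled); the high/low split is then applied to
the *unfiltered* image at `split_threshold_frac = 0.35` of the
within-body maximum. The split fraction is a configurable placeholder
calibrated on the synthetic phantom — the optimal clinical threshold is
camera-dependent and should be tuned per site. Both thresholds are
relative to image maxima, so whole-body contrast matters: the pipeline
segments the 2-h study, where counting statistics and body-to-organ
contrast are best, and reuses those masks at the later time points
(compartment geometry does not move between scans of the same fraction).

## Kinetics

The low compartment is fitted with a constrained biexponential
($a_1, a_2 \ge 0$, $\lambda_1 \ge \lambda_2 > 0$) by bounded
Levenberg–Marquardt least squares, initialised from a log-linear fit of
the last two points and the early-point residuals. With four points and
four parameters the noiseless fit is exact; degenerate fits (collapsed
rate constants, vanishing amplitude, non-convergence) fall back to a
mono-exponential fitted in log space. A slow rate constant below the
$^{177}$Lu physical decay constant (0.004345 /h) triggers a warning,
since whole-body clearance cannot be slower than physical decay.

The high compartment uses a linear segment through the first two points
(back-extrapolated to $t = 0$ and clamped at zero) and an exponential
tail fitted by log-linear least squares over points 2–4. Two choices here
were genuinely open and are resolved as follows. First, the tail is a
least-squares fit over all three later points rather than a two-point
solve, because it uses all the data. Second, the tail is anchored at the
regression's own prediction at $t_2$, not at the measured second point;
the resulting (small) junction discontinuity against the measurement is
reported via a message rather than hidden by re-anchoring, so a
systematic mismatch is visible in logs. A non-decaying tail is clamped at
$\lambda = 10^{-6}$ /h with a warning.

Time-integrated activities are analytic: $a_1/\lambda_1 + a_2/\lambda_2$
for the biexponential, and the exact integral of the clamped linear
segment plus `tail_value`$/\lambda$ for the piecewise form. The tests
compare these against adaptive quadrature (with an analytic remainder
beyond 2000 h) to 0.1% over 200 random fitted curves. The hybrid scale
factor evaluates the *fitted* concentration curve at 24 h rather than the
raw 24-h measurement — the fitted value is noise-robust and consistent
with the integral that multiplies it.

## SPECT VOIs

Vertebral bodies are sampled with 0.7 cm³ spheres (radius 5.51 mm) placed
at centres supplied in a table — automatic vertebra detection is out of
scope. Voxel membership is by voxel-centre-in-sphere without
partial-volume weighting: simple, convergent under grid refinement, and
adequate because the sphere is deliberately smaller than the vertebral
body to avoid partial-volume and cross-contamination effects. SPECT
volumes are assumed reconstructed, scatter/attenuation corrected,
calibrated to kBq/mL and resampled to the CT grid upstream.

## Cohort statistics

The toxicity endpoint is the relative platelet nadir (nadir/baseline), so
dose-response correlations are negative. Spearman's $r_s$ is the Pearson
correlation of mid-ranks; its two-sided p value is exact by full
permutation enumeration for $n \le 9$ (valid under ties) and uses the
t approximation otherwise. The Wilcoxon rank-sum p value is exact by
enumeration of all group assignments for combined $n \le 12$ (mid-ranks,
so also valid under ties) and otherwise uses the tie-corrected normal
approximation without continuity correction. Both are cross-checked in
the tests against `cor.test()`/`wilcox.test()` where those provide exact
nulls, and against independent brute-force enumeration. Significance is
$\alpha = 0.05$ on raw p values; no multiplicity adjustment is applied,
matching how such per-cell correlations are conventionally reported.
Fraction-1 correlations use the fraction-1 dose; fraction-2 correlations
use the cumulative dose.

## What the synthetic generators emulate

The planar phantom projects a two-compartment body (organ ellipses about
an order of magnitude above background in projected concentration) with
every source a uniform slab centred in the body thickness, so the
conjugate-view assumptions hold exactly and the noiseless pipeline must
return the generating truth. Poisson counting noise is optional and
seeded. Default kinetics (low: fractions 0.62 at 0.20/h + 0.11 at
0.020/h; high: linear rise to a 0.20 peak fraction at 24 h, tail
0.012/h) were chosen once to give whole-body retention, organ contrast,
24-h vertebra-to-background ratios near 3, and marrow doses in the
clinically reported 0.1–0.5 Gy/7.4 GBq range.

The SPECT generator stacks spherical vertebral bodies over a uniform
background. The cohort generator draws 46 patients (52% male, 52%
skeletal-metastasis prevalence, 6.8–8.0 GBq per fraction, two fractions,
baseline platelets lognormal around 241×10⁹/L) with lognormal patient
effects on kinetics (CV 0.15) and on a vertebral axial profile taken from
a published 22-patient reference (peak between T10 and L1; CV 0.25),
per-vertebra visibility probabilities from that cohort's field-of-view
counts, a 1.13 male/female L1–L4 concentration ratio, a diffuse
metastasis elevation factor (default 1.3) plus individually flagged hot
vertebrae, and a platelet response
$\mathrm{clamp}(1 - 0.7\,D_{cum} + \mathcal N(0, 0.12),\ 0.05,\ 1.2)$
driven by the generator's own ground-truth dose.

What the generators do **not** emulate: anthropomorphic anatomy, organ
overlap in projection, camera point-spread functions, SPECT
reconstruction artefacts, scatter fields, marrow fat-fraction physiology,
or platelet dynamics beyond a noisy monotone dose response. Passing tests
therefore demonstrate the *correctness of the computational chain* under
its stated assumptions, not clinical accuracy on real images.

## Numerical choices and degenerate inputs

* Self-attenuation factor $x/\sinh x$ evaluated by series for
  $|x| < 10^{-4}$, so $\mu_{eff} = 0$ is handled exactly.
* Zero counts in either view give zero activity; an all-zero image is an
  error, as are masks that exhaust the L4 fallback chain.
* The segmentation's $\ge$-threshold rule makes a uniform image entirely
  high-uptake (documented edge semantics); high and low always partition
  the whole-body mask exactly.
* Median with an even count is the mean of the central pair throughout.
* Exact-test cutoffs ($n \le 9$ permutations, $n \le 12$ assignments)
  keep enumeration below ~4×10⁵ cases; permutation index matrices are
  cached per $n$.
* Configuration files are YAML; tables are tidy CSV with snake_case
  headers; images are NIfTI.
* S factors are shipped as a per-sex, per-organ table of stated synthetic
  approximations (masses at adult reference values, photon S factors of
  order 10⁻⁷–10⁻⁸ Gy/(MBq·h) built from the ~33 keV photon yield per
  decay and body-scale specific absorbed fractions). Every dose result
  records the provenance string of the table that produced it. For
  clinical use, replace this table with site-validated values via
  `default_s_factors(path = ...)`.

## Validation problem sizes

The shipped validation uses a 148×68-pixel phantom at 0.5 cm pixels
(noiseless round trip; 100 Poisson replicates), 200 random kinetic
parameter draws for the quadrature comparison, exhaustive rank-test
enumeration up to $n = 9$ (Spearman) and $n = 8$ (rank-sum), a
46-patient default cohort, and a 20-seed cohort bank for the
fraction-2-versus-fraction-1 comparison. These sizes make the full suite
run in well under a minute while leaving the statistical checks
well-powered.

## Limitations

The method inherits the limitations of its clinical template: a single
abdominal thickness for the whole body, one fixed organ thickness, no
organ-level subdivision of the high compartment, photon-only cross dose,
electron-only self dose, and a marrow surrogate that ignores fat-fraction
variation with age and sex. The hybrid methods are sensitive to which
vertebrae are visible and to metastatic infiltration — reproducing, in
the synthetic cohort, the qualitative pattern that hybrid doses are
higher and their dose-response correlations stronger once metastases are
present, while the planar method's fixed ratio washes patient-specific
marrow uptake out of its estimate.
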