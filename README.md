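# marrowdose

Image-based bone marrow dosimetry for ¹⁷⁷Lu-DOTATATE peptide receptor
radionuclide therapy (PRRT), written for medical physicists and dosimetry
researchers who need a tested, fully scriptable implementation of the
planar two-compartment marrow dose method and its four SPECT/CT hybrid
variants, together with the cohort-level dose–toxicity statistics used to
evaluate them.

## The problem and the model

Bone marrow is, next to the kidneys, the organ at risk in PRRT, but its
activity cannot be imaged directly: red marrow is dispersed in small
cavities, mixed with fat, and may be infiltrated by skeletal metastases.
The approach implemented here treats the whole body as two compartments
segmented from anterior/posterior planar scintigraphy at 2, 24, 48 and
168 h after injection — a *high-uptake* compartment (liver, spleen,
kidneys, tumours) and a *low-uptake* compartment (everything else), whose
activity concentration serves as the marrow surrogate.

The marrow absorbed dose is assembled MIRD-style from a self-dose term and
two photon cross-dose terms:

```
D_BM = C̃_BM · φ(BM←BM) · Δ  +  Ã_low · S(BM←low)  +  Ã_high · S(BM←high)
```

where `Ã` are time-integrated activities from analytic integrals of the
fitted time–activity curves (biexponential for the low compartment; a
linear rise between the first two points followed by a log-linear
exponential tail for the high compartment), `Δ = 147 keV` is the locally
absorbed electron energy per ¹⁷⁷Lu decay, `φ(BM←BM) = 1`, and the `S`
factors are organ-mass-weighted photon cross-dose factors per sex.  The
marrow time-integrated concentration `C̃_BM` is the low-compartment
concentration scaled by either

* a fixed ratio **1.8** (the *planar* method), or
* a patient-specific ratio measured with a 0.7 cm³ sphere VOI placed in a
  vertebral body on SPECT/CT at 24 h (the *hybrid* methods): the L4
  vertebra with an L4→L5→L3→L2 metastasis fallback chain (**L4-SPECT**),
  or the median concentration over all visible (**V-SPECT**), lumbar
  (**L-SPECT**) or thoracic (**T-SPECT**) vertebrae.

At a scale factor of exactly 1.8 the hybrid equation reduces to the planar
one — a property the test suite checks to machine precision.  Cohort
dose–response is quantified as the Spearman correlation between absorbed
dose (fraction dose after fraction 1, cumulative dose after fraction 2)
and the relative platelet nadir (nadir/baseline), with exact permutation
p values in small samples, and Wilcoxon rank-sum comparisons between
patient groups.

Because clinical images are not distributable, the package includes
first-class synthetic generators — a projection phantom whose geometry
satisfies the conjugate-view assumptions exactly, a vertebral SPECT volume
builder, and a 46-patient cohort simulator with known ground-truth doses —
so every stage is validated end to end against known truth.

## Worked example

```r
library(marrowdose)

## camera calibration from a Petri-dish depth series
cal <- fit_attenuation_sensitivity(
  depths = c(0, 4, 8, 12),                      # cm
  count_rates = c(980, 608.5, 377.9, 234.7),    # cps
  true_activity = 98.2)                         # MBq
cal
#> Gamma-camera calibration (camera)
#>   sensitivity : 9.97898 cps/MBq
#>   mu_eff      : 0.119103 /cm
#>   RMS log-fit residual: 6.07e-05 (n = 4 depths)

## conjugate-view quantification of a compartment
conjugate_view_activity(ant_counts = 1.2e6, post_counts = 0.95e6,
                        duration_s = 1800, calib = cal,
                        body_thickness_cm = 21)   # 199.9 MBq

## kinetics of the low-uptake compartment
low_fit <- fit_low_curve(c(2, 24, 48, 168), c(3900, 560, 330, 29))
low_fit
#> Biexponential TAC: A(t) = 4767 exp(-0.2213 t) + 872.5 exp(-0.02026 t)
#>   time-integrated activity: 64599 MBq*h

## marrow dose, planar and hybrid
masses <- compartment_masses(78000, 320, 21)      # body, area, thickness
conc   <- to_concentration(low_fit, masses$m_low)
s      <- default_s_factors("male")
inp    <- dose_inputs(integrate_curve(conc), integrate_curve(low_fit),
                      150000, s, administered_gbq = 7.5)
bone_marrow_dose_planar(inp)
#> Bone marrow dose (planar), fraction 1:
#>   dose: 0.1656 Gy (self 0.1383 + cross 0.02725)
#>   normalised: 0.1634 Gy/7.4 GBq (administered 7.5 GBq)
bone_marrow_dose_hybrid(inp, hybrid_scale_factor(28.2, conc), "L_SPECT")
#> Bone marrow dose (L_SPECT), fraction 1:
#>   dose: 0.3031 Gy (self 0.2758 + cross 0.02725)
#>   normalised: 0.299 Gy/7.4 GBq (administered 7.5 GBq)
```

The planar estimate (fixed 1.8 ratio) is roughly half the hybrid estimate
here because this patient's vertebral concentration at 24 h is about 3.3
times the low-compartment concentration — the typical pattern that
motivates patient-specific hybrid dosimetry.

`run_pipeline()` chains all stages (calibrate → simulate → segment →
quantify → fit → dose → statistics) on a seeded synthetic cohort and
writes tidy CSV tables plus a run manifest; `simulate_cohort()` generates
the statistical cohort directly.

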