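---
title: "Methods: serial whole-body PET dosimetry and pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial whole-body PET dosimetry and pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

`petdosim` turns sparse serial whole-body PET measurements — three scans,
a few urine collections, a short plasma sampling series — into organ
absorbed-dose coefficients, an effective dose, plasma kinetics and cohort
uptake statistics. This vignette is the package's account of the methods:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Time base and decay arithmetic

All times are minutes post-injection with injection at zero; a scan's time
point is the start of its whole-body acquisition (acquisition mid-times are
not modelled; users with exact per-organ clock times can simply pass them).
The nuclide is a parameter everywhere, defaulting to a 68-min half-life
positron emitter, so limiting cases (λ → 0) and other isotopes can be
exercised. Decay correction is the exact exponential round trip; negative
elapsed times are an error rather than an implicit back-extrapolation.

## SUV

SUV uses body-weight normalisation at unit tissue density:
`SUV = C·W/A0`. Lean-body-mass or BSA variants are deliberately not
offered — the downstream statistics compare like with like, and the
clinical tables the package reproduces use body weight.

## From concentrations to TIACs

Dosimetry integrates *decay-uncorrected* activity. Organ activity is
estimated as concentration × reference organ volume, with the phantom organ
volume scaled by the patient-to-phantom total-mass ratio; "scaled for
patient weight" is read as volumetric scaling, the simplest defensible
choice when no CT segmentation is used. The fraction-of-injected curve is
integrated:

* trapezoidal rule across the sampled interval;
* a **linear rise from zero** at injection to the first sample. With first
  imaging around 10 min this is the conservative standard; note that for a
  curve already decaying at `t1` it *under*-integrates the leading segment.
  On the 3-point clinical schedule the net bias for a purely decaying
  region is about −3.5 % (the leading-triangle deficit outweighs the
  trapezoid's overshoot on convex decay). On dense grids (≤ 0.1 min) the
  integrator matches analytic mono- and bi-exponential integrals to 0.1 %,
  which is the property the test suite enforces; the sparse-schedule bias
  is a property of the study design, not of the integrator.
* an analytic tail `A(tn)/λ` beyond the last sample — **physical decay
  only**, no fitted terminal slope, because extrapolating biologic
  clearance from three points is not identifiable and physical-decay-only
  is the conservative (dose-overestimating) choice.

TIACs are validated against the physical bound `Σ ã ≤ 1/λ` (1.6350 h per
unit injected for a 68-min half-life). Cohort TIACs are arithmetic means
over patients; a region missing in some patients is averaged over the
patients reporting it (missing ≠ zero), with the per-region n recorded.

## Urinary excretion and the voiding bladder

Cumulative decay-corrected urine activity, as a fraction of injected
activity, is fitted to the one-phase exponential association
`U(t) = F(1 − e^{−kt})` by bounded Levenberg–Marquardt least squares
(start: `F0` = max observed fraction, `k0 = ln2/60`; bounds `F ∈ [0,1]`,
`k ∈ (0,1]`). The **pooled** fit across patients is the default — the
cohort bladder dose uses one excretion function — with a per-patient mode
for diagnostics. The fitted plateau `F` is used as-is, not renormalised to
total eventual excretion 1: the data cannot distinguish slow late excretion
from retention, and renormalising would overstate the bladder dose.

The bladder model assumes complete, instantaneous voiding every `T_v`
minutes (default 60), first void at `T_v`. Between voids the physical
bladder content is `B(t) = e^{−λt}[U(t) − U(t_j)]`; the TIAC sums
`∫ B dt` over cycles until the bound on all remaining cycles falls below
10⁻⁶ of the accumulated value (well inside the 0.01 % horizon criterion).
Decays occurring in *voided* urine — `Σ_j e^{−λ t_j} ΔU_j / λ` — are
tracked separately so the whole-body balance closes:

```
remainder = 1/λ − voided − bladder − Σ explicit organs   (floored at 0)
```

The remainder is a derived, flagged quantity: it is what the dose engine
needs as a source region, not a measurement.

## Dose engine

The MIRD schema is a matrix product: `D = S ã`, linear in the TIACs, with
an explicit alias table for source naming (by default the blood-pool TIAC
— kept as a diagnostic region because the underlying data report a
distinct, declining blood pool — is folded into the remainder source, since
S-value tables carry no separate blood compartment). Effective dose is the
ICRP-103 tissue-weighted sum of sex-averaged organ doses with radiation
weighting factor 1 (positrons/photons), so mGy/MBq and mSv/MBq coincide
numerically; single-phantom input is allowed with an explicit caveat
message. Reports print coefficients to 3 significant figures; tests always
compare unrounded values.

The shipped phantom masses and S-values are **synthetic fixtures**
(filenames say so): plausible adult-male masses, and S-values from a
local-beta-absorption plus uniform-photon-bath model with a bladder-wall
surface term at half the contents' self-dose rate. They make the pipeline
runnable and physically coherent (self-dose dominates cross-dose; the
bladder wall tops the dose table under renal excretion) but are not a
reproduction of any proprietary dose-factor library — reproducing a
specific study's printed organ coefficients additionally requires that
study's per-patient VOI data.

## Plasma pharmacokinetics

Per-patient mono-exponential fits `C(t) = C0 e^{−kt}` (log-linear
initialisation, then nonlinear least squares). Plasma input is
decay-corrected, so the fitted half-life is biologic clearance. The cohort
summary is the **mean of per-patient half-lives** with the min–max range —
not `ln2 / mean(k)`, which is systematically smaller; the two differ by
Jensen's inequality and the per-patient mean is what clinical reports
quote. Non-decaying series are flagged and excluded from the cohort mean
with a warning rather than fitted blindly.

## Cohort uptake statistics

Summaries are mean ± SEM with the n−1 sample standard deviation (the
denominator convention is asserted in tests); n = 1 yields SEM 0 with a
flag. Rounding is half-away-from-zero and applied only at report time.
Tumor-to-organ ratios are computed per patient (lesion SUVmax over organ
SUVmean) and averaged second — a mean of ratios, not a ratio of means.
Where a table reports one lesion per organ, the lesion with the highest
SUVmax is selected, ties broken by lesion id for determinism. The packaged
uptake table includes one patient whose values refer to a liver metastasis
(primary unknown); the record is flagged but included in group means,
matching the arithmetic of the printed cohort summaries.

## The synthetic cohort

The generator emulates the study conditions end-to-end: two groups of 5
patients, whole-body sampling at {10, 60, 120} min, urine and plasma in a
7-patient subset, administered activity N(184.4, 38.4²) MBq truncated to
[97.3, 220], weights uniform on 55–95 kg. Each organ follows an
uptake–washout model; as a decay-uncorrected fraction,

```
A_r(t) = f_r · k_u/(k_u − k_w) · (e^{−k_w t} − e^{−k_u t}) · e^{−λt}
```

whose integral is available in closed form, so every patient carries an
*analytic* ground-truth TIAC. Default kinetics are kidney/liver-dominant
with a fast-equilibrating declining blood pool and near-zero
brain/lung/bone/muscle concentrations; the urinary plateau is F = 0.55 at
k = 0.02/min, giving a renal share of excretion above 80 % (the remaining
route being intestinal retention). These values were chosen once as a
qualitative match to a renally cleared small peptide tracer and are not
fitted to any dataset. Uptake fractions plus the excreted fraction must
sum to ≤ 1 or generation refuses to start; per-patient jitter that would
break the balance is rescaled back inside it.

Noise is multiplicative log-normal on concentrations (CV 5 % by default,
mean-one so zero-noise tests are exact), applied to urine *increments* so
cumulative series stay monotone. Plasma half-lives are uniform on 3.9–14.0
min. All draws come from one stream keyed by the seed, ordered by
(patient, region, time), so identical (config, seed) pairs are
byte-identical on disk.

What passing the synthetic tests shows: the integrators, fitters and dose
algebra are correct against closed forms, parameters are recoverable at
realistic noise, and the chain is deterministic. What it does not show:
performance under VOI delineation error, partial-volume effects, motion,
reconstruction bias, non-instant voiding, multi-exponential excretion or
inter-organ kinetic correlation — none of which the generator simulates.

## Problem sizes and tolerances used by the tests

Zero-noise TIAC recovery is checked on a dense 1-min schedule to 300 min
(3 % tolerance, dominated by the physical-decay-only tail over a slowly
washing-out organ); dense-grid oracle agreement at 0.1 %; closed-form
bladder cases at 0.1 %; excretion and plasma recovery medians over 200
noisy replicates at 5 %; Monte-Carlo sizes were chosen to make the medians
stable at fixed seeds while keeping the default suite around ten seconds.

## Known limitations

* Organ masses are phantom-referenced and weight-scaled, not personalised.
* The tail assumption (physical decay only) overestimates TIACs for organs
  that keep clearing biologically after the last scan.
* The voiding model idealises collection times to a fixed interval.
* Single-phantom effective dose is a caveated approximation of the
  male/female mean reference quantity.
* The synthetic S-matrix supports validation, not clinical dose reporting.
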