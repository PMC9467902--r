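---
title: "Microdialysis pharmacokinetics of intraperitoneal carboplatin: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microdialysis pharmacokinetics of intraperitoneal carboplatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipecMD)
```

## The measurement problem

During hyperthermic intraperitoneal chemotherapy (HIPEC) a heated
carboplatin solution is circulated in the abdominal cavity for 90 minutes.
How much drug the abdominal organ tissues actually see — and for how long —
is the quantity of interest, and microdialysis is the sampling tool: a
semipermeable catheter perfused at 1 µL/min collects, per timed interval,
a dialysate whose concentration is a *fraction* of the true free tissue
concentration. The pipeline in this package turns those dialysates into
per-compartment pharmacokinetic parameters in four stages: retrodialysis
calibration, recovery correction, non-compartmental analysis (NCA), and
group summaries/comparisons.

### Calibration and correction

The fraction recovered is the relative recovery,
$RR = 100\,(1 - C_{dial}/C_{perf})$, estimated per catheter after the
sampling period by perfusing a known 100 µg/mL solution and averaging two
40-min samples (`catheterRecovery()`). Correction inverts the attenuation:
$C_{tissue} = 100\,C_{dial}/RR$ (`correctConcentration()`), and each
corrected value is assigned to the midpoint of its collection interval.
Because a dialysate is a time-average, the midpoint convention is itself an
approximation; its bias is what the oracle tests quantify (below).

Catheters whose calibration is invalid — an apparent $RR \le 0$ means the
dialysate matched or exceeded the perfusate, i.e. malfunction — are excluded
*whole*: none of their study samples are used and no compartment-mean RR is
substituted. This mirrors per-catheter accounting in practice, where losses
are reported as whole catheters (the default 8 × 8 design loses 3 to
malfunction and 8 to displacement, leaving 53).

### Non-compartmental analysis

Per animal × compartment profile:

* **Cmax/Tmax**: maximum observed point; ties broken by earliest time
  (a convention; it only matters on exactly tied values).
* **AUC$_{0\text{-last}}$**: linear up-log down trapezoid — linear on rising
  or flat segments, log-linear on falling ones. The log rule assumes
  exponential decline between points and never exceeds the linear rule
  (log-mean inequality); this ordering is enforced as a property test. A
  falling segment ending at a non-positive value falls back to the linear
  rule. The area starts at $t = 0$ with concentration zero — tissue contains
  no carboplatin before perfusion begins — rising linearly to the first
  midpoint. This leading-segment choice is configurable (`leadingZero`)
  because the $t=0$ handling is a genuine free choice in NCA; zero is the
  physically forced default here.
* **$\lambda_z$, T$_{1/2}$**: OLS of log concentration on time over a
  terminal tail of points strictly after Tmax. The point-selection rule is
  not dictated by the method definition, so it is an explicit policy object:
  the default examines every tail of the last $k \ge 3$ points and keeps the
  one with maximal adjusted $R^2$ and positive slope (ties to the shortest
  tail, deterministic); `"last3"` is available as the fixed alternative.
  With only 4–7 post-peak points in a 480-min window, a clean terminal phase
  often does not exist, so T$_{1/2}$ is reported with an estimability flag
  rather than forced.

### Summaries and comparisons

Per-compartment summaries are arithmetic means with two-sided 95 %
t-intervals across animals — deliberately plain, model-free intervals.
Between-compartment comparison fits, by REML, a linear mixed model with
compartment fixed and animal as random intercept, and reports the overall
F-test plus pairwise paired t-tests on within-animal differences (complete
pairs only), unadjusted by default with an optional Holm switch. Small-sample
denominator degrees of freedom are the classical repeated-measures values
($(a-1)(c-1)$ balanced, $N-a-c+1$ otherwise), which coincide with the
Satterthwaite approximation under balanced compound symmetry; a
Kenward–Roger correction is deliberately out of scope, and for two
compartments the F-test is exactly the squared paired t (tested).

## The synthetic study: what it emulates

`simulateStudy()` generates a complete study under a stated world chosen
once:

* **Design**: 8 animals, weights evenly spaced over 71–83 kg (only the range
  is known, so a uniform spread is the least-committal choice), 800 mg/m²
  dosing via $SA = 0.0970\,W^{0.633}$, 12 samples per catheter on the
  30/60-min schedule, LOQ 0.100 µg/mL, calibration perfusate 100 µg/mL.
* **Truth curves**: per-compartment double-exponential (Bateman) kinetics
  $C(t) = A(e^{-k_e t} - e^{-k_u t})$. This form has closed-form Cmax, Tmax,
  AUC and half-life (`closedFormNCA()`) — the analytic oracles every
  pipeline stage is tested against — and can place Tmax after the 90-min
  perfusion, the key qualitative phenomenon. Each compartment's $(A, k_u,
  k_e)$ is calibrated (`kineticsFromPeak()`) so its closed-form Cmax and
  Tmax equal the reported population means (Cmax 10.6–26.0 µg/mL, Tmax
  105–206 min across compartments), with a fixed uptake/elimination ratio
  $k_u/k_e = 4$ supplying the remaining degree of freedom.
* **Recovery**: per-catheter true RR drawn from a normal with the
  per-compartment means/SDs (75.2–93.1 % means), truncated to (0, 100] by
  redraw — RR is a fraction by definition.
* **Noise**: multiplicative lognormal with unit mean; CV interpolated
  linearly in $\log_{10}$(concentration) between the assay's five printed
  intermediate-precision points (20.8 % at 0.100 µg/mL down to 3.5 % at
  30 µg/mL), clamped outside. All measurement error is attributed to the
  assay ladder since no separate within-catheter residual estimate exists.
* **Censoring**: values below LOQ are flagged and reported at the LOQ
  marker, as an assay reports "<LOQ". The default analysis policy excludes
  them with bookkeeping; LOQ/2 imputation is available behind
  `loqPolicy = "halve"` for sensitivity analysis, since how below-LOQ
  dialysates were handled in practice is unstated.
* **Dropout**: independent per-catheter malfunction/displacement with
  probabilities 3/64 and 8/64 — the observed study rates.
* **Seeding**: all randomness flows through `set.seed(config@seed)`; the
  truth record (`SimTruth`) plus the config reproduce a dataset exactly.

### What the generator does *not* emulate

* **No between-animal kinetic variability**: all animals share each
  compartment's truth curve, so simulated between-compartment contrasts are
  far sharper than in real data, where animal-to-animal variation dominates
  and few contrasts reach significance. Significance patterns from
  `mixedModelCompare()` on simulated data therefore say nothing about real
  tissue differences; the F-test is instead validated on null simulations
  (empirical type-I error at $\alpha = 0.05$ within [0.01, 0.10]).
* **Late-time tail heights**: with Cmax and Tmax pinned to the reported
  means and a smooth Bateman shape, the high-Cmax compartments keep more
  drug at 450 min than the 4.9–9.9 µg/mL reported across tissues. Matching
  the tail as well would need a third calibration target the stated world
  does not include.
* No perfusate-volume/temperature dynamics, no end-of-perfusion perfusate
  concentration (not derivable from the stated inputs), no tumour-tissue
  heterogeneity, no partial salvage of samples from displaced catheters
  (full exclusion is assumed).

Hence a green oracle test establishes that the pipeline recovers the
parameters of the stated world — it does not validate the biology of any
particular study.

## Numerical choices

* **Oracle agreement**: on noise-free, RR = 100 simulations the pipeline
  profile equals the closed-form interval averages bit-for-bit (the RR
  factor is applied as `rr/100` so that RR = 100 multiplies by exactly 1).
  The discretized AUC to the last observation (450 min) agrees with the
  closed-form AUC over $[0, 450]$ to within ~1 % on the default kinetics —
  comparing like with like: AUC "to last sample" is bounded by the last
  *observed* time, and halving the interval widths provably shrinks the
  error (tested).
* **$\lambda_z$ accuracy**: the fitted rate approaches $k_e$ only once the
  selected tail is past the uptake phase; the recovery test asserts the 5 %
  agreement whenever the selected tail spans at least two terminal
  half-lives, which the slow default compartments (half-lives 150–460 min)
  never reach inside the 480-min window — their T$_{1/2}$ values are
  reported but flagged accordingly.
* **Degenerate guards**: a numerically-zero slope (|λ| ≤ 1e-12/min) or a
  constant tail is non-estimable, not an error; a paired t-test on
  identically equal values returns $t = 0, p = 1$ without calling
  `t.test()` on zero variance.
* The peritoneum peak concentration appears once in its source with the
  unit misprinted as "g/mL"; it is treated as µg/mL, consistent with the
  stated 10.6–26.0 µg/mL range.

## Limitations

Beyond the generator's simplifications: the mixed-model df convention is an
approximation (documented above); AUC is not extrapolated to infinity and no
clearance/volume parameters are derived; plasma protein binding is not
modelled (microdialysis measures free drug, and plasma samples pass through
uncorrected); and the LOQ policies bracket, but cannot resolve, the
treatment of censored values in any particular historical dataset.
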