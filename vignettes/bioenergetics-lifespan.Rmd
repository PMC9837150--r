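---
title: "Methods: from extracellular flux to lifespan analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from extracellular flux to lifespan analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolifespan)
```

`mitolifespan` implements the quantitative core of a longitudinal
cellular-bioenergetics study design: primary fibroblasts with and without
OxPhos defects are cultured to replicative arrest while extracellular flux,
growth, and molecular markers are measured repeatedly. This vignette
explains the models and conventions behind each stage, the parameters that
matter, and what the synthetic-data generators do and do not emulate.

## ATP production rates from extracellular flux

A MitoStress-style run partitions oxygen consumption with three sequential
injections: oligomycin blocks the F~0~F~1~ ATP synthase (leaving proton
leak plus non-mitochondrial respiration), FCCP uncouples to reveal maximal
electron-transport capacity, and rotenone/antimycin A abolish mitochondrial
respiration altogether, leaving the non-mitochondrial floor. The classical
decomposition follows by subtraction:

- non-mitochondrial = rot/AA floor; basal mitochondrial = basal − floor;
- ATP-linked = basal − oligomycin; proton leak = oligomycin − floor;
- maximal = FCCP − floor; spare = maximal − basal mitochondrial;
- coupling efficiency = ATP-linked / basal mitochondrial;
  respiratory control ratio = maximal / proton leak.

**Phase summarization.** A phase contributes one representative value:
last basal cycle, minimum under oligomycin, maximum under FCCP, minimum
after rotenone/antimycin A, and basal ECAR as the basal-phase mean. These
statistics follow common extracellular-flux practice — inhibition takes a
cycle or two to reach its plateau, so the extreme within the phase is the
cleanest estimate of the inhibited (or uncoupled) state — and they are
arguments of `summarize_phases()`, not constants.

**QC rather than clamping.** Subtraction can produce negative rates
(instrument drift, incomplete inhibition). Negative derived rates are kept
as computed and flag the well (`negative_atp_linked`, `negative_ppr_glyc`,
…); a well whose basal mitochondrial respiration is not positive is flagged
`nonrespiring` and yields a null ATP flux with a reason. Group aggregation
(`aggregate_group()`) averages unflagged wells with equal weight and
reports how many wells were excluded; there is no automatic outlier-well
rejection.

**Stoichiometry.** Conversion to ATP fluxes uses a named constant set
(`stoichiometry_preset("glucose_mookerjee")`), assuming energy sourced
entirely from glucose, with values from Mookerjee *et al.* (2017, J Biol
Chem 292:7189): P/O~oxphos~ = 2.486 ATP per O atom, 1 ATP per exported
lactate, 0.334 ATP per O~2~ of glycolytic substrate-level phosphorylation
coupled to glucose oxidation, and respiratory acidification of
H⁺/O~2~ = 1/(1 + 10^(pK~1~−pH)) ≈ 0.953 at pH 7.4, pK~1~ 6.093. The
buffering-power default (0.1566 mpH per pmol H⁺) corresponds to a nominal
2.8 mmol·L⁻¹·pH⁻¹ assay-medium buffer factor in a 2.28 µL measurement
microchamber; it is the constant users should most expect to recalibrate
for their own media. Fluxes are homogeneous of degree 1 in the raw
OCR/ECAR, and `j_total = j_ox + j_glyc` holds exactly by construction.

## Replicative lifespan

Population doublings per passage are `log2((live + dead)/plated)` — dead
cells divided before dying, so they count toward replicative age — and may
be negative if the population shrank. Two replicative-arrest rules are
implemented because both appear in practice: the default terminates when
the division rate stays below 0.01 divisions/day for two consecutive
passages (the Hayflick limit is the cumulative doubling count at the second
such passage); the alternative terminates on the first 30-day window with
less than one doubling. A trajectory that never meets the rule is
*censored* at its final doubling count — a status, not an error.

**Windowed contrasts.** Lifespan-average group effects use configurable
day windows (defaults: 20–150 days for lifespan effects, 20–50 for
early-life effects, 25–75 for epigenetic-aging slopes). Group means are
computed in two stages — within donor, then across donors — so a donor with
more timepoints does not dominate; the paper-style alternative of pooling
all timepoints is deliberately not offered, since donors are the
experimental unit.

**Mixed-effects tests.** `lmm_group_test()` fits
`value ~ group + day + (1|donor)` by maximum likelihood and tests the group
effect with a likelihood-ratio comparison against the model without
`group`; batches of markers are corrected by Benjamini–Hochberg. The χ²
reference for the LRT is asymptotic in the number of donors: our null
simulations reject at ~12% with 3 donors per group and only approach the
nominal 5% as the donor panel grows. The package's calibration experiments
therefore use 24 donors/group × 6 timepoints; with the 3-donor designs
typical of fibroblast studies the p-values should be read as
anti-conservative, which is a limitation of the method, not of the
implementation.

**Trajectory fits and rates.** Polynomial trajectory fits default to cubic;
a quintic is adopted only when ≥ 8 points are available and it lowers the
small-sample-corrected AIC (AICc), replacing a subjective "kinetic
complexity" judgement with an explicit criterion. Aging-rate slopes are
ordinary least squares; the relative rate change versus control is
`100 × (slope_treat − slope_ctrl)/slope_ctrl`, with the *signed* control
slope in the denominator so that a 2.62-fold faster telomere attrition
reads as +162% whether the slopes are negative (T/S per doubling) or
positive (DNAm-age per day).

## qPCR markers

mtDNA copy number uses the ΔCt method, `2^(Ct_nuc − Ct_mt) × 2`, the final
factor accounting for the diploid nuclear reference. Triplicates pass a
three-step ladder: Ct > 33 discarded; if CV (SD/mean of Ct) exceeds 0.02
the set is inspected and a value more than 2 SD from the mean of the
*other* replicates is removed (at most one — note that with n ≤ 3 no value
can be 2 sample-SDs from its own set's mean, so the leave-one-out form is
the only operative reading); if the final CV exceeds 0.1 the sample is
rejected. All steps append flags, and a reported mean never includes a
flagged value.

Telomere T/S ratios rely on standard curves (Ct vs log10 quantity; at
least three standards spanning two decades; amplification efficiency
`10^(−1/slope) − 1`), Dixon's Q at α = 0.05 (critical-value table shipped
for n = 3–7 and α = 0.10/0.05/0.01) for triplicate wells, and duplicate-run
reconciliation: runs agreeing within 7% (relative to the initial run) are
averaged; otherwise a third run decides and the two closest values are
averaged. Estimating quantities through the standard curve — rather than
assuming perfect doubling — is what makes copy-number recovery robust to
sub-unity amplification efficiency.

## Deletions and cohort meta-analysis

Deletion calls (consumed from breakpoint tables; the caller itself is out
of scope) are filtered at a strict heteroplasmy cutoff (default > 5%),
lengths respect the circular 16,569-bp genome (a deletion spanning the
origin wraps), unique deletions are distinct breakpoint pairs within a
timepoint, and the lifespan burden is the sum of per-timepoint unique
counts — a definition chosen for transparency where the field has no fixed
convention; duplications are tallied separately. The heteroplasmy column is
accepted as percent or fraction, auto-detected by range and logged.

Cohort effects use Hedges' g (pooled SD, small-sample correction
`J = 1 − 3/(4N − 9)`), percent differences on group means, the Weir
equation `REE = 1.44 × (3.94·VO₂ + 1.11·VCO₂)` (kcal/day, gas rates in
mL/min, optionally per kg), and unweighted cohort pooling — cohorts with
only aggregate means still contribute percent differences, just not g.

## The synthetic-data generators

Each generator inverts its analysis stage from declared ground truth, so
zero-noise data reproduce the truth to floating-point rounding and noisy
data quantify recovery. All randomness flows through one sub-stream per
generated object, derived from the master seed and a label, so adding a
generator never shifts existing outputs.

- **Plates** (`simulate_plate()`): from a (J_ox, J_glyc) truth, phase
  plateaus are composed using a 0.2 proton-leak fraction, a 0.15
  non-mitochondrial fraction, and a 2× FCCP/basal ratio; measurements get
  multiplicative Gaussian noise (instrument-like). Scenario presets encode
  the study conditions: controls at a 64:36 OxPhos:glycolysis balance;
  a SURF1-like arm at 23:77 with 1.91× total ATP demand; an oligomycin-like
  arm at 10:90 with doubled demand.
- **Growth curves** (`simulate_lifespan()`): division rate declines
  linearly (logistic optional) from 0.5/day (controls) across ~220 days,
  giving a control replicative limit near 55 doublings; the SURF1-like and
  oligomycin-like arms reach limits 53% and 40% lower. Noise is lognormal
  on the per-passage doubling count, which keeps doublings nonnegative —
  real terminal cultures can shrink, so threshold-monotonicity of the
  Hayflick estimate is asserted only on such nonnegative trajectories.
- **qPCR** (`simulate_qpcr()`): Ct = intercept − log2(q)/log2(1 + E) with
  duplex-assay noise — a well-level component (SD 0.1 Ct) shared by the
  mitochondrial and nuclear channels of the same well, plus a half-sized
  channel-specific component — and optional injected +5 Ct outliers to
  exercise the QC ladder.
- **Markers and cohorts**: linear series plus additive noise (telomere
  attrition −0.010 T/S per doubling in controls, 2.62× steeper in the
  SURF1-like arm; DNAm-age 0.2 yr/day, 2.31× faster), and cohort summary
  tables drawn from the sampling distributions of means and SDs.

What the generators do **not** emulate: within-phase injection kinetics
(phases are plateaus), non-glycolytic ECAR sources beyond respiratory CO₂,
plate-position and edge effects, donor-level biological heterogeneity in
flux truths, mtDNA deletion accumulation dynamics, and assay drift across
runs. Passing recovery tests therefore demonstrates correctness of the
conversions and estimators under the stated noise models, not robustness to
every artifact of real plates.

## Numerical choices and problem sizes

Tolerances: "exact" identities are asserted to ≤ 1e−12 relative (pure
floating-point rounding); noisy-recovery assertions use the generator's
known sampling variability. Ties in QC outlier removal break toward the
higher Ct (later-amplifying wells are the more likely artifact). Degenerate
inputs (zero range in Dixon's Q, zero division rate, all-flagged groups)
return explicit statuses rather than NaN arithmetic. Simulation sizes in
the test suite — 50 replicate plates of 10 wells, 500 qPCR samples, 200
null and 100 coverage mixed-model fits at 24 donors/group — were chosen so
each recovery estimate's Monte-Carlo error is comfortably below the margin
being asserted while the full suite stays fast.
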