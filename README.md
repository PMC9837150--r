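# mitolifespan

Longitudinal cellular bioenergetics and replicative lifespan analytics.

Primary fibroblasts carrying oxidative-phosphorylation (OxPhos) defects —
genetic (e.g. *SURF1* mutations) or pharmacological (chronic low-dose
oligomycin) — can be profiled repeatedly across their replicative lifespan:
extracellular-flux assays, passage-level growth records, qPCR markers
(mtDNA copy number, telomere length), mtDNA deletion calls, and cohort-level
clinical summaries. `mitolifespan` implements the computational layer of
such a study as tested, reusable R functions, for cell biologists and
biostatisticians who want the conversions and statistics to be explicit and
auditable rather than buried in vendor software or one-off scripts.

## What it computes

**ATP production rates from extracellular flux.** A MitoStress-style run
(basal → oligomycin → FCCP → rotenone/antimycin A) is summarized per phase,
partitioned into respiratory components, and converted into ATP fluxes
using explicit stoichiometric constants (glucose preset after Mookerjee
*et al.* 2017, J Biol Chem 292:7189):

- J_ATP-OxPhos = 2 × P/O<sub>oxphos</sub> × OCR<sub>ATP-linked</sub>
  (proton leak and non-mitochondrial O₂ consumption excluded),
- PPR<sub>glyc</sub> = ECAR/BP − (H⁺/O₂) × OCR<sub>mito</sub>,
- J_ATP-Glyc = PPR<sub>glyc</sub> × ATP/lactate + P/O<sub>glyc</sub> ×
  OCR<sub>mito</sub>,
- J_ATP-Total = J_ATP-OxPhos + J_ATP-Glyc (an exact identity by
  construction), with per-cell / per-volume / per-division normalization.

**Replicative lifespan.** Population doublings `log2((live+dead)/plated)`
per passage, cumulative doubling trajectories, Hayflick limits under two
termination rules (division rate < 0.01/day for two consecutive passages,
or < 1 doubling per 30 days), windowed group contrasts with two-stage donor
averaging, mixed-effects group tests (`value ~ group + day + (1|donor)`,
likelihood-ratio p, Benjamini–Hochberg q), cubic/quintic trajectory fits,
and linear aging-rate slopes (telomere T/S per doubling, DNAm-age per day).

**qPCR markers.** mtDNA copies/cell = 2^(Ct<sub>nuc</sub> −
Ct<sub>mt</sub>) × 2 with a three-step triplicate QC ladder (Ct > 33
discarded; CV > 0.02 inspected with 2-SD outlier removal; CV > 0.1
rejected); telomere T/S standard curves with Dixon's Q and 7% duplicate-run
reconciliation; cell-free mtDNA/nDNA ratios.

**Deletions and cohorts.** mtDNA deletion-burden summaries at a
heteroplasmy cutoff on the circular genome, and cohort-level effect sizes:
percent differences, Hedges' g with small-sample correction, Weir-equation
resting energy expenditure `REE = 1.44 × (3.94·VO₂ + 1.11·VCO₂)`, and
unweighted cohort pooling with one-sample/paired t-tests.

**Synthetic data.** Seeded generators invert each analysis stage from known
ground truth (ATP fluxes, Hayflick limits, copy numbers, attrition slopes,
cohort effects), so every pipeline stage is verifiable offline.

## Worked example

```r
library(mitolifespan)
k <- stoichiometry_preset()               # glucose constants
sim <- simulate_plate(scenario_preset("control"), n_wells = 4,
                      noise_sd = 0.05, seed = 1)
wells <- process_plate(sim$traces, injection_scheme(), k)
round(wells[, c("j_ox", "j_glyc", "j_total", "ox_fraction")], 3)
#>       j_ox  j_glyc  j_total ox_fraction
#> 1 1329.395 714.180 2043.575       0.651
#> 2 1386.677 673.606 2060.283       0.673
#> 3 1435.112 687.360 2122.472       0.676
#> 4 1221.526 711.024 1932.549       0.632
aggregate_group(wells, value = "ox_fraction")
#>     group      mean         sd n n_excluded reason
#> 1 control 0.6579518 0.02068615 4          0   <NA>
```

Each row is one well: `j_ox`/`j_glyc`/`j_total` are ATP production rates in
pmol ATP/min/well attributed to OxPhos, glycolysis, and their sum;
`ox_fraction` is the OxPhos share of total ATP supply. The group summary
averages unflagged wells only (here, none excluded) and recovers the
generator's 64% OxPhos ground truth from the noisy traces.

```r
growth <- simulate_lifespan(r0 = 0.5, lifespan_days = 220,
                            noise_sd = 0.05, seed = 1)
hayflick_limit(build_trajectory(growth$records), rule = "rate")
#> $status      "terminated"
#> $hayflick_pd 55.35021
#> $day         225
hedges_g(14, 2, 3, 10, 2, 3)$g
#> [1] 1.6
```

The growth curve reaches replicative arrest at ~55 cumulative population
doublings, and the effect-size engine reproduces the textbook Hedges' g
arithmetic (d = 2, J = 0.8).

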