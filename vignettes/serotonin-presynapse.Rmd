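---
title: "Modelling genotype-driven serotonin presynapse dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genotype-driven serotonin presynapse dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodyn)
```

## Why simulate the presynapse?

Presynaptic serotonin (5-HT) turnover cannot be measured directly in living
cohorts, yet it is the quantity that hypotheses about suicidality and mood
disorders actually concern. What *can* be measured cheaply is genotype at a
handful of functional variants whose effects on the expression of the three
controlling proteins are known from allelic-imbalance and reporter assays:
tryptophan hydroxylase 2 (TPH2, synthesis), the serotonin transporter (SERT,
reuptake) and monoamine oxidase A (MAOA, degradation). `serodyn` turns each
individual's genotype into a personalised simulation of the presynapse and
compares the simulated molecular profiles between clinical groups.

The pipeline has four stages, each usable on its own:

1. **Genotype → activity coefficients** (`compute_activity()`).
2. **Coefficients → concentration time courses** (`simulate_trajectory()`),
   by integrating a kinetic ODE model.
3. **Time courses → 30 features** (`extract_features()`): mean, median,
   maximum, standard deviation, skewness and kurtosis for each of 5-HTP,
   fc5-HT, v5-HT, e5-HT and 5-HIAA.
4. **Features → group statistics** (`kw_features()`, `art_anova()`,
   `art_posthoc()`).

## From genotype to protein activity

Each variant's alleles carry an expression multiplier relative to the
reference allele (G at rs111798998 ≈ 3-fold; A at rs7305115 ≈ 1.7-fold; A at
rs4290270 ≈ 1/1.4; 5-HTTLPR L ≈ 3-fold; MAOA uVNTR 4R/3.5R ≈ 5–6-fold,
default 5.5, the midpoint of the reported range). Three modelling choices
here are genuinely open and are therefore isolated and configurable:

* **Within a variant**, the two alleles' multipliers combine by their
  arithmetic mean — additive expression of two gene copies. This sits in a
  single function (`variant_coefficient()`) so a dominance-style rule could
  be swapped in without touching anything else.
* **Across the three TPH2 variants**, per-variant coefficients combine
  multiplicatively. Haplotype phase is unobserved, so the three SNPs are
  treated as independent; a haplotype-aware rule would need phased input
  that the genotype-table format does not carry.
* **X-linkage**: males carry one MAOA allele and contribute its multiplier
  directly; heterozygous females get the plain mean of their two alleles.
  Modelling X-inactivation skew would require single-cell assumptions with
  no data behind them here.

The all-reference genotype maps to (1, 1, 1) for either sex, and the
reachable coefficient space is small and fully enumerable —
`enumerate_activity_grid()` lists all 27 × 3 × 3 = 243 triples — which is
what makes exhaustive property checking (and fast cohort simulation via
per-triple caching) possible.

## The kinetic model

Eight states (all µM): extracellular and intracellular tryptophan, 5-HTP,
free cytosolic 5-HT (fc5-HT), vesicular 5-HT (v5-HT), extracellular 5-HT
(e5-HT), 5-HIAA, and a cumulative `cleared` pool that closes the mass
balance. The genotype-scaled steps are Michaelis–Menten with the activity
coefficient on Vmax only — fold-changes in mRNA are taken to change protein
*abundance*, not catalytic efficiency, so Km is never scaled. All other
steps (AADC decarboxylation, vesicular release, the two clearance paths)
are first order. 5-HIAA removal (`k_hiaa`) is deliberately identical for
every individual: between-person differences in simulated 5-HIAA then
reflect synthesis and routing, never elimination.

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) at rtol 1e-8 /
atol 1e-10, sampled on a uniform 1-minute grid over 600 minutes following
a single 100 µM dietary tryptophan pulse. Identical inputs give
bit-identical trajectories. Negative solver noise up to 1e-12 µM is clipped
to zero and counted; anything larger aborts. Since every reaction is a 1:1
molar transformation, the eight-state total is conserved under pulse input;
`mass_balance()` audits this (residuals are ~1e-14 in practice, against a
1e-6 test ceiling). A constant-infusion variant of the model admits an
algebraic flux-balance solution (`steady_state()`, closed-form where
possible plus one monotone 1-D root), which the test suite uses as an
integration oracle: the long-run ODE solution must converge to it
componentwise. At steady state the cumulative `cleared` pool necessarily
grows at the infusion rate, so the stationarity check applies to the seven
concentration states.

### Choosing the default rate constants

The published presynapse model this package re-implements does not ship its
rate constants, so the defaults here are a **phenomenological calibration**,
not literature values: they were chosen once so that the model sits in the
qualitative regime the source system is described to occupy, and they are
all overridable (`kinetic_defaults()`). Three regime conditions drove the
calibration:

* **TPH2 is rate-limiting throughout.** `vmax_tph2 = 0.25` µM/min leaves
  part of the tryptophan load unconverted at 600 min even for the largest
  synthesis coefficient (5.1). This is what makes every downstream pool
  strictly monotone in `c_tph2`: at larger Vmax the pulse is fully consumed
  for every genotype and mean 5-HTP collapses to a genotype-independent
  constant (differences of ~1e-6, with orderings flipping inside solver
  noise).
* **5-HIAA removal is slow relative to the window.** `k_hiaa = 0.001`/min
  (timescale 1000 min) makes 5-HIAA accumulate toward a late peak, so its
  sampled distribution is left-skewed — skewness between −1.92 and −0.38
  across the full genotype enumeration, bracketing the ≈ −0.4 regime the
  modelled system reports. With fast removal the 5-HIAA course peaks early
  and decays, and its skewness changes sign.
* **MAOA controls the fate of serotonin, not just its timing.** Cytosolic
  5-HT is partitioned between vesicular packaging (`vmax_vmat = 0.75`,
  `km_vmat = 0.3`) and MAOA degradation at comparable capacities, and
  clearance of the extracellular pool is diffusion-dominated at the
  compartment scale modelled here (`k_eloss = 10`/min against a SERT
  recapture of `vmax_sert = 0.1`, `km_sert = 0.2`): released serotonin
  mostly leaves the cleft, and SERT recycles only a few percent per pass.
  Under these constants the MAOA coefficient sets the *share* of
  synthesised serotonin that ends up as 5-HIAA (≈ 14% at `c_maoa = 1` to
  ≈ 47% at 5.5). In the alternative regime where nearly all serotonin is
  eventually recycled into MAOA's path, `c_maoa` moves only the timing of
  5-HIAA accumulation and genotype groups become statistically
  indistinguishable at realistic cohort sizes.

These choices interact — the third condition is what gives the synthetic
end-to-end power study its ≈ 95% detection rate — and they were frozen
before the acceptance battery was finalised. Nothing in the package treats
the resulting *absolute* concentrations as reproduction targets; only sign
and ordering properties are asserted.

## Feature conventions

The six statistics use population (biased) central moments: `sd = √m2`,
`skew = m3 / m2^1.5`, and Pearson non-excess kurtosis `m4 / m2²` (a normal
series scores 3; a linear ramp 1.8). The non-excess convention is the one
consistent with ramp-like concentration series clustering a little below 2.
Sample-corrected and excess variants are available as arguments. Statistics
are computed over the full uniform grid including t = 0. A constant series
has `m2 = 0`; it reports skewness and kurtosis 0 with a `degenerate` flag
rather than NaN, so downstream rank tests never see missing values.

Interpretation note: for an accumulating metabolite sampled over a fixed
window, *more negative skewness means later accumulation* — the
concentration spends most of the window near its late plateau. This is why
5-HIAA skewness functions as a proxy for the timing of serotonin turnover.

## The statistical battery

Normality screening (Shapiro–Wilk), Mann–Whitney, tie-corrected
Kruskal–Wallis and the chi-square test of independence (Yates-corrected for
2 × 2) wrap the standard `stats::` implementations in tidy, tibble-returning
form; the test suite checks them against exhaustive enumeration oracles on
all layouts up to n = 8. Significance is labelled at p < 0.05 with p in
(0.05, 0.10] flagged as a trend.

The two-way **Aligned Rank Transform ANOVA** is implemented in-package. For
each effect (diagnosis, SA status, interaction) the response is *aligned* —
within-cell residual plus that effect's own estimated contribution, with
the other effects' cell-mean contributions removed, margins taken as
unweighted means of cell means — then mid-ranked, and a full two-factor
fixed-effects ANOVA is fitted on the ranks (`lm` with sum-to-zero
contrasts, Type-III sums of squares via `car::Anova`), keeping only the
target effect's F and p. Unweighted margins and Type III are the standard
conventions for unbalanced between-subjects factorials and make the
alignment exact: on noiseless factorial data the off-target effect
estimates left in an aligned response are zero to machine precision, which
`art_align()` reports as a diagnostic and the tests assert at 1e-10. Post
hoc contrasts (`art_posthoc()`) are Tukey-adjusted pairwise `emmeans`
contrasts on the factor-aligned ranks. Across the 30 features the package
reports raw per-feature p-values (matching the analysis layout it mirrors);
a Benjamini–Hochberg column is available behind the `bh` flag and is
clearly an addition, not part of that layout.

Calibration, measured by the acceptance battery: on 1,000 null datasets at
the study's six cell sizes (46/55/76/72/53/90), each effect rejects at
0.047–0.048 against the nominal 0.05.

## Synthetic cohorts

`default_study_design()` encodes the modelled study's layout exactly: 392
patients in six diagnosis × SA cells (BD 46/55, MDD 76/72, SCH 53/90) plus
140 unaffected individuals, with each cell's exact female count and age
mean/SD. Genotypes are drawn under Hardy–Weinberg equilibrium within each
cell (two independent allele draws; one draw per X for the MAOA uVNTR in
males), with per-cell deterministic substreams so resizing one group never
perturbs another's draws. The default allele frequencies (G 0.35, A 0.40,
A 0.45, L 0.55, 4R 0.35, 3R 0.60, rare alleles ≤ 0.02) are configurable
placeholders in the common population range — the frequencies of the
original cohort are not published, and no asserted property depends on
their exact values. Linkage between the TPH2 SNPs is ignored (independent
draws); ages are optional and feed only the demographic table.

What the synthetic cohorts do **not** emulate: linkage disequilibrium and
haplotype structure, population stratification, relatedness, genotyping
error, and any genotype–environment interplay. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline's statistics behave
correctly under its stated sampling assumptions — not that the biological
effect sizes in real cohorts match.

### Power and calibration studies

`inject_effect()` shifts one allele's frequency within one diagnosis group
(rescaling the rest proportionally, reversibly), creating a detectable
group effect. The packaged power study shifts uVNTR 4R by +0.3 in SCH at
n = 200 (Table-style cells scaled down) and recovers a significant ART
diagnosis effect on mean 5-HIAA in ≈ 95% of 200 replicates, while neutral
cohorts reject at ≈ 5%.

One subtlety is deliberate: the power-study cells share a **common female
fraction** (65%). Because MAOA is X-linked, hemizygous males and diploid
females have differently shaped activity distributions, and the
genotype-to-feature map is nonlinear — so groups with different sex ratios
differ in expected 5-HIAA even under identical allele frequencies. With the
study's real (sex-imbalanced) cells this inflates the "neutral" rejection
rate to ~0.10: a genuine property of X-linked biology, not a test artifact.
Balancing sex across cells isolates the injected genotype effect; analyses
of real cohorts should treat sex composition as a confounder for
MAOA-driven features.

## Problem sizes used by the checks

The exhaustive enumeration covers all 243 coefficient triples at the full
600-minute grid; ART calibration uses 1,000 simulated datasets at n = 392;
the recovery study uses 200 replicate cohorts of n = 200 against a
precomputed per-triple feature cache (`build_feature_cache()`), which is
also the natural way to run many cohorts under one parameter set.

## Known limitations

* The kinetic constants are calibrated to a qualitative regime, not fitted
  to data; absolute concentrations are illustrative.
* No receptor or postsynaptic signalling, no other neurotransmitter
  systems, no pharmacological effects, no gene–environment modulation.
* The eighth state is a bookkeeping pool for cleared material; alternative
  closures (e.g. explicit efflux compartments) would change nothing
  observable but would change the mass-balance audit.
* ART ANOVA here is the between-subjects two-factor case only; no
  repeated-measures or covariate adjustment (sex and age are compared
  descriptively, not modelled).
* Heavily tied responses (few distinct genotype triples at small n) push
  rank tests toward discreteness; the calibration results above were
  measured under exactly those conditions.
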