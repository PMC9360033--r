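---
title: "Methods: molecular classification, risk stratification and multi-state modelling in AML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular classification, risk stratification and multi-state modelling in AML}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amlclass)
```

This vignette documents the models and procedures implemented in
`amlclass`, the assumptions behind them, the parameters that matter,
and the design choices made where the design was genuinely open. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The classification model

AML genotypes are summarised as a *lesion profile*: a set of coded
cytogenetic abnormalities from a controlled vocabulary plus oncogenic
mutation calls in a gene panel. We deliberately consume pre-coded
lesion tokens (e.g. `t(15;17)`, `+8`, `del(5q)`, `-7`) rather than
free-text ISCN karyotype strings: processed AML cohorts are typically
distributed with per-lesion binary columns, and an ISCN parser is a
separate engineering problem with its own failure modes.

Classification is a *first-match rule hierarchy* over 16 classes.
The bundled order (configurable via a YAML file) is:

1. t(15;17) — 2. inv(16) — 3. t(8;21) — 4. KMT2A/t(11;x) — 5. t(6;9) —
6. inv(3) — 7. TP53/complex — 8. trisomies — 9. sAML2 — 10. biCEBPA —
11. NPM1 — 12. sAML1 — 13. DNMT3A/IDH — 14. WT1 — 15. mNOS —
16. no events.

The principles behind the order: established WHO-style fusion entities
precede everything; TP53/complex precedes the mutation-defined
classes; sAML2 precedes biallelic CEBPA; the catch-alls close the
hierarchy, which makes assignment total — every profile, including an
empty one, receives exactly one class.

Key predicates and the reasoning behind their edges:

- **Complex karyotype** is ≥3 unbalanced abnormalities with the
  restriction that at least one unbalanced lesion is not a
  whole-chromosome gain. Without that restriction a karyotype of three
  or more trisomies would be "complex" and the trisomy class — a
  distinct, more favorable entity even with ≥3 gains — could never be
  reached.
- **TP53/complex** fires on an oncogenic TP53 mutation *or* a complex
  karyotype: the two findings co-occur in roughly two thirds of
  complex-karyotype patients and form one prognostic entity.
- **Trisomies** requires ≥1 gain and no deletions or whole-chromosome
  losses. Co-occurring balanced abnormalities are tolerated (the
  criterion concerns aneuploidy patterns, not translocations); this
  choice is configurable in spirit but hard-coded, as the alternative
  only reroutes profiles that also carry a higher-ranked fusion.
- **sAML1/sAML2** count *distinct* mutated genes among the 11
  class-defining secondary-AML features. MLL contributes only through
  partial-tandem-duplication calls; other MLL mutations are ordinary
  panel findings.
- **biCEBPA** requires ≥2 distinct oncogenic CEBPA calls as a
  biallelic proxy; single CEBPA mutations are not class-defining.
- **WT1** and **DNMT3A/IDH** sit after the larger classes, so they
  only fire "in the absence of classifying events".
- **FLT3-ITD is never class-defining.** We apply this strictly: an ITD
  call does not even count toward the mNOS "any remaining driver"
  predicate, so a profile whose only finding is FLT3-ITD classifies as
  `no_events`. This keeps the invariant that toggling ITD never
  changes a patient's class — the property the risk shift rules rely
  on. Non-ITD FLT3 point mutations do count toward mNOS.
- A missing karyotype is treated as "no cytogenetic lesions" for the
  rules and recorded on the assignment, so mutation-defined classes
  remain reachable.

The bundled 32-gene panel keeps every explicitly named class-defining
gene and fills the remainder with canonical recurrent AML drivers; it
is a representative default, and `load_panel()` accepts a replacement
file for any local assay.

## TP53 allelic state

Multi-hit state requires one of: ≥2 TP53 mutations; ≥1 mutation plus
loss of the TP53 locus (del(17p), −17, or a focal 17p deletion); or ≥1
mutation at VAF > 65%, read as loss of heterozygosity. A single
mutation with none of these is mono-allelic. VAF may be missing, in
which case the LOH criterion simply cannot fire — we do not impute
VAFs.

## Risk stratification

The ELN2017 three-tier genetic table is implemented as the reference.
Two implementation decisions: FLT3-ITD allelic ratio ≥ 0.5 counts as
"high", and an ITD with *missing* ratio is treated as high — the
conservative reading, which only affects the reference, never the
proposed score. t(15;17) is placed favorable (APL sits outside the
formal ELN2017 table, but the classifier includes it, so the
reference must place it somewhere; non-adverse is the only defensible
choice). RUNX1/ASXL1 adversity does not override the favorable
molecular subtypes, while TP53 and adverse cytogenetics do.

The proposed score maps each class to a base tier — Favorable-P:
t(15;17), inv(16), t(8;21), biCEBPA, NPM1, no events; Intermediate-P:
sAML1, trisomies, WT1, DNMT3A/IDH, t(6;9), mNOS, KMT2A;
Adverse-P: sAML2, TP53/complex, inv(3) — then applies two shift
rules: NPM1 class with FLT3-ITD moves one tier down to Intermediate-P,
and *any* Intermediate-P patient with FLT3-ITD moves to Adverse-P.
Shifts move exactly one tier, never improve a stratum, and ignore the
ITD allelic ratio entirely. KMT2A's base tier is not stated in the
class-to-tier enumeration we follow; we default it to Intermediate-P
(it then shifts to Adverse-P with ITD) and expose the whole map as a
config file. Likewise only NPM1 is named for the favorable-tier shift,
so biCEBPA and the other favorable classes never shift.

## The six-state multi-state model

States: alive after induction (1), alive in CR (2), relapse (3), death
without CR (4), death in CR (5), death after relapse (6); transitions
1→2, 1→4, 2→3, 2→5, 3→6. All transitions run on the *time from
diagnosis* clock (clock-forward). Patients with
inconsistent timepoints (relapse without CR, times out of order,
missing follow-up) are excluded and reported rather than repaired. A
death with a recorded relapse time routes through the relapse state; a
death in CR without relapse is a 2→5 event. We chose the forward clock
because clinical trajectories are conventionally read against time
from diagnosis, and a clock-reset model would change the meaning of
the baseline hazards; clock-reset is a reasonable alternative we did
not take.

The non-parametric estimator is Aalen–Johansen: Nelson–Aalen hazard
increments per transition, product-integrated into occupancy
probabilities. Rows of P(t) sum to 1 by construction and
absorbing-state occupancy is monotone. A guard clips the (rare,
tiny-risk-set) case of a hazard increment exceeding 1 so P stays a
distribution.

The semi-parametric layer fits one Cox model per transition,
h_ij(t|Z) = h_ij0(t) exp(β′_ij Z), with **Breslow** tie handling and
Breslow baseline increments at Z = 0 (the standard baseline estimator
consistent with that tie option). Prediction scales
each baseline by exp(β′z) and product-integrates; with zero covariates
this reproduces the Aalen–Johansen estimator to numerical precision,
which the tests assert at 1e−8.

Per-transition covariate **medians** are computed on that transition's
at-risk records and serve two purposes: unspecified covariates are
imputed at the median (so the calculator's "parameters not specified"
policy is exact), and the contributing-factor decomposition
β_ij·(Z − Z_ij,median) is zero exactly at the median. Negative factors
indicate lower-than-median risk for that transition.

Confidence bands for occupancy curves resample *patients* (not
records), refit all transitions, and take percentile intervals;
default 200 replicates. Both the replicate count and the percentile
method are package choices, made for robustness over speed.

Covariates outside the training 2.5–97.5% range trigger an outlier
warning on the prediction (returned, not raised as an error), mirroring
the calculator's warning-sign behaviour for under-supported inputs.

## Dirichlet-process clustering

The class-discovery procedure is a DP mixture over the binary
patient-by-lesion matrix, fit by collapsed Gibbs sampling in the
Chinese-restaurant representation with Escobar–West resampling of the
concentration parameter under a Gamma(shape, rate) hyperprior. For
binary lesion indicators the Bernoulli–Beta base measure is the
natural conjugate choice and is the default; a Gaussian base — which
some practitioners prefer when mixing binary with scaled continuous
features — is provided as an option, selectable per fit.

Algorithmic details we fixed: 300 sweeps with 100 burn-in and
thinning 5 by default; the reported partition is the posterior sample
minimising the least-squares distance to the posterior co-assignment
matrix (a standard deterministic summary); per-patient assignment
probabilities are post-burn-in co-assignment frequencies against the
final components, mapping each sample's clusters to final components
by maximal overlap. Fixed seed gives identical output.

Component merging applies a cosine-similarity threshold with
transitive closure. The two-step fit re-runs the sampler on the
patients whose top assignment probability falls below the confidence
threshold (default 0.7, exposed as a parameter — there is no single
canonical value for this cutoff).
Grid search scores configurations lexicographically on (1) the number
of high-confidence components, (2) mean top assignment probability,
(3) mean top1−top2 delta, with ties kept in grid order. Post-processing
enforces that a patient is only assigned to a component whose defining
lesion they carry (demoting the rest toward the mNOS pool), and manual
splits partition a mixed component by a discriminating lesion —
patients eligible for more than one component resolve by highest
assignment probability.

The package validates the *procedure* on planted-partition matrices
(signal 0.9 vs background 0.02, K ∈ {2,3,5}, n = 300, five seeds,
adjusted Rand ≥ 0.9); reproducing any specific historical clustering
of a real cohort would require that cohort and its manual curation and
is out of scope.

## Comparison harness

The IPCW concordance index weights each admissible pair by the inverse
squared Kaplan–Meier censoring-survival at the earlier event time.
We adopt Uno-type truncation of the earlier event at the 95th
percentile of observed follow-up as the default (the standard
stabiliser against near-zero censoring-survival weights), with
`tau = Inf` available — under zero censoring and no truncation the
statistic is exactly Harrell's C, which the tests assert to 1e−12
against a brute-force pair enumeration.

The comparison workflow is a single 75/25 train/validation split,
learner fitting on the training side, held-out C-index, bootstrap
resampling of the held-out patients (100 resamples) for 95% intervals,
and two-sided z-scores on the bootstrap standard errors for pairwise
p-values, unadjusted for multiplicity. Learners are pluggable
(`fit(X, time, status) → function(newX) → risk`); the bundled learner
is elastic-net Cox over the mixing grid 0 to 1 in 0.2 steps with
internal 5-fold cross-validation of the penalty weight. Boosting,
random-survival-forest and SVM backends are deliberately not bundled;
the contract accepts any of them.

Permutation importance permutes one feature at a time (50 permutations
by default) and reports the mean ratio of reference to permuted
C-index; ratio ≈ 1 marks an uninformative feature, and the measure is
direction-blind by design.

## The synthetic generator

The generator is the package's study population. Class prevalences
default to the class frequencies reported for large AML trial cohorts
(TP53/complex 10.3%, trisomies 11.2%, sAML2 23.7%, sAML1 4.7%, WT1
2%, DNMT3A/IDH 1%, mNOS 6%, no events 2.2%) with the remaining mass
over the fusion classes and NPM1 (25%) — chosen once and fixed.
Genotypes are emitted class-conditionally: class-defining lesions with
probability 1 in strict mode, characteristic co-mutations at rates
typical of these entities (TP53 in 65% of complex-karyotype patients,
FLT3-ITD in 70% of t(6;9)), and, critically,
*no lesion from an earlier hierarchy rank* —
which is what makes strict-mode cohorts exactly recoverable and the
round-trip test meaningful. Noisy mode injects cross-class
contaminating lesions with a configurable probability to study
degradation. Clinical covariates are class-conditional (older
complex-karyotype and secondary-AML-like patients with more antecedent
hematologic disease and lower blasts, young high-WBC WT1 patients).

Trajectories draw competing exponential transition times scaled by
exp of class, age and FLT3-ITD log hazard ratios, with uniform
administrative censoring (2.5–8 years by default). Baselines
(1.8, 0.65, 0.45, 0.11, 0.8 per year for the five transitions) were
set so the state flow reflects the pattern seen in intensively treated
adult AML: ~70% reach CR, about half of CR patients relapse, and most
relapses are fatal. What the generator does **not** emulate: within-class
co-mutation correlation structure beyond the emission rates, VAF
distributions (one value per call), time-varying hazards, or
treatment effects — so passing tests demonstrate correctness of the
machinery on a faithful state-flow model, not calibration to any real
cohort.

One caution established while validating: when the generator includes
class/age/ITD effects and a Cox fit includes only a subset of them,
the omitted effects act as frailty and attenuate coefficients — a
well-known property of proportional-hazards models, not an estimation
defect. Parameter-recovery tests therefore run with homogeneous
baselines and the injected covariate as the only effect.

## Numerical and scale choices

- Problem sizes in the tests: exhaustive classifier enumeration over a
  10-lesion/8-gene universe (2^18 profiles, vectorised engine);
  counting-oracle agreement at n = 200; hazard-ratio recovery at
  n = 2000; 50-replicate mean-recovery at n = 1000; clustering
  recovery at n = 300 with 200 sweeps. These sizes give stable
  assertions at interactive runtimes.
- Ties: event-time ties are handled by Breslow throughout; risk-score
  ties count 1/2 in concordance.
- Degenerate inputs: empty cytogenetics yield zero karyotype features;
  an all-zero lesion matrix yields one mixture component; a transition
  with zero events is flagged unestimable rather than fitted.
- All stochastic code paths take explicit seeds; identical seeds give
  identical outputs, including the full two-step clustering path and
  the calculator's bootstrap bands.

## Known limitations

- The ELN2017 implementation covers the genetic table only
  (no clinical modifiers), and the classifier targets the 16-class
  schema — no WHO2016 mapping, no ICC/ELN2022.
- The cytogenetics vocabulary is the coded-token set above; rare
  lesions must be mapped to `other_balanced`/`other_unbalanced` by the
  caller.
- The multi-state model assumes Markov transitions on the forward
  clock; history effects (e.g. CR duration influencing post-relapse
  survival) are not modelled.
- The bundled gene panel's non-class-defining tail is a representative
  default, not a transcription of any specific assay.
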