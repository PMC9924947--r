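---
title: "Linking stress resistance to longevity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking stress resistance to longevity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspan)
```

# The scientific problem

Long-lived *C. elegans* mutants from different longevity pathways
(insulin/IGF-1 signaling, dietary restriction, reduced translation, mild
mitochondrial impairment, elevated mitochondrial ROS, reduced chemosensation,
germ-line ablation) tend to resist external stressors better than wild type.
`stresspan` implements the quantitative framework for asking, within a single
panel measured under common conditions:

1. how much longer each mutant lives than its matched control;
2. how resistant each strain is to each of a panel of stressors, and whether
   that resistance is statistically significant;
3. how strongly each form of stress resistance — and aggregate summaries of
   resistance — predicts lifespan extension across strains;
4. which genes' expression tracks each phenotype across strains; and
5. whether the gene sets behind stress resistance and behind longevity are
   the same genes, quantified by observed/expected overlap enrichment.

Every stage is exercised end-to-end on synthetic cohorts with planted ground
truth, so the pipeline's operating characteristics (type-I error, power,
false-discovery control, null behavior of enrichment ratios) are measured
rather than assumed.

# Survival machinery

Individual animals contribute `(time, event)` records; censored animals
(`event = 0`, e.g. removed for internal hatching) are handled by the
product-limit (Kaplan–Meier) estimator. Conventions:

* **Ties.** Censoring ties at a death time are counted at risk at that time
  and removed afterwards (right-continuous convention). Tied deaths use the
  exact hypergeometric variance term — no approximation.
* **Mean survival.** Without censoring, the arithmetic mean of death times;
  with censoring, the restricted mean (area under the KM step function up to
  the largest observed time). Published survival panels typically report
  "average survival" without defining how censoring is handled; the
  restricted mean is the standard estimand that degrades gracefully, and it
  reduces to the arithmetic mean when no animal is censored.
* **Fraction alive at `t`.** Animals censored at or before `t` leave the
  denominator (status unknown); everything observed beyond `t` counts as
  alive.
* **Two-sample tests.** One weighted-log-rank core provides both the
  Mantel–Cox log-rank (weight 1) and the Gehan–Breslow–Wilcoxon test
  (weight = total number at risk, emphasizing early differences), each
  referred to the chi-square distribution on 1 df. Both are symmetric in
  group order. The log-rank chi-square p agrees with a label-permutation p
  to within 0.02 on 30-per-arm data (checked in the acceptance suite).
* **Control-vs-many.** One-way ANOVA with Dunnett's two-sided many-to-one
  comparison. The adjusted p-value `P(max_j |T_j| >= |t_i|)` is evaluated by
  Monte Carlo over the equicorrelated multivariate t distribution
  (`corr(T_i, T_j) = sqrt(lambda_i lambda_j)`, `lambda_i = n_i/(n_i+n_0)`),
  with 10^5 draws and a fixed internal seed, giving ~0.005 reproducible
  accuracy on adjusted p. The reference sample is cached per design, so
  panel-wide and simulation use costs one build. With a single treatment
  group the procedure reduces to the two-sided t-test within Monte-Carlo
  error; the implementation cross-checks against `multcomp` in the test
  suite. Homogeneous variances are assumed (pooled mean squared error), as
  in the classical procedure.

# From assays to strain phenotypes

Each assay is described by an `assay_spec`: endpoint kind (fraction alive at
a fixed time, or mean survival), endpoint time, and the significance test.
The default panel mirrors the classic worm battery — lifespan (days), heat
37°C and acute oxidative stress scored at 10 h, chronic oxidative stress and
bacterial slow-killing scored to death (days), osmotic stress at 48 h,
anoxia at 72 h. Fixed-time proportion assays are tested by Dunnett over
replicate proportions jointly across all strains sharing the standard
control; survival-curve assays use the log-rank test per strain. A strain
flagged as requiring the alternate-temperature control (the germ-line-ablation
analog, which must develop at 25°C) is compared to its own control by
Student's t-test.

Strain-level summaries:

* **Lifespan extension (%)** = `100 · (mutant mean − control mean) / control
  mean`.
* **Direction call**: `increased` / `decreased` / `unchanged` at α = 0.05
  (the conventional threshold at which figure asterisks begin).
* **Relative score**: each assay's endpoints rescaled so the best strain
  scores 100%; scale-invariant, which makes hours, days and proportions
  commensurable.
* **Combined stress score**: the unweighted mean of the six relative scores.
  The mean (not the sum) keeps the score on a 0–100 scale while ranking
  strains identically.
* **Resistance count**: the number of stressors with an `increased` call.
  When one stressor is probed at two severities, the default policy counts
  the stressor if either level is significant (configurable to require
  both).

Missing assays are excluded with a warning, never imputed.

# Cross-strain association

`linear_fit` is ordinary least squares with the slope p-value from the t
distribution on n−2 df; a constant response returns R² = 0 and p = 1 rather
than an error, since "no association" is the correct scientific reading.
`phenotype_lifespan_correlations` regresses lifespan extension on every
stress endpoint, the combined score, and the resistance count.

`gene_phenotype_correlation` correlates one expression summary per strain
with a strain-level phenotype. Choices and defaults:

* **Summary**: per-strain mean of `log2(normalized count + 1)`
  (`"log2_mean"`), or that minus the matched control's summary (`"lfc"`).
  The fold-change mode respects the alternate-temperature control; the
  log2-mean mode retains wild type as an anchor point and is what the
  parameter-recovery analyses use.
* **Correlation**: Pearson by default (the summaries are already on the log
  scale); Spearman by flag — a choice that published analyses of this kind
  usually leave unstated, hence configurable here.
* **Significance**: raw p < 0.05 by default — appropriate when the
  correlated-gene lists are consumed as broad sets, which is how thousands
  of correlated genes out of ~20k detected arise — with a BH-q-gated rule
  (`criterion = "q"`) configurable for recovery-style analyses where the
  false-discovery proportion must be controlled.
* Genes with zero variance across strains are excluded and reported; p = 0
  is reported for numerically perfect correlation.

`multiplicity_counts` decomposes per-stressor significant sets into exact-k
membership counts (how many genes correlate with exactly k stressors); the
counts sum to the union size by construction.

# Overlap enrichment

For gene sets A and B in a universe of N genes, the expected chance overlap
is `|A|·|B|/N`; fold enrichment is observed/expected; significance is the
upper-tail hypergeometric probability P(X ≥ k), computed through `phyper`
(log-space internally, stable far beyond transcriptome scale). Percent
overlap divides by the reference set — the stress-correlated set by
convention (the denominator used in published overlap figures).
Flat ORA over GMT term maps uses the same tail (identical to the one-sided
Fisher exact test) with BH q-values across terms; no GO-DAG propagation is
attempted.

The universe matters: enrichment ratios are sensitive to it, and the source
study never states its universe. It is therefore an explicit configuration
value, defaulting to the genes passing the expression filter (mean
normalized count ≥ 1 in at least one strain).

# Differential expression

The DE stage is intentionally minimal: median-of-ratios size factors
(upper-quartile fallback when no gene is nonzero everywhere), then a
per-gene test on `log2(normalized + 1)` — Welch's t without the batch flag,
or the strain coefficient of the additive model `expression ~ strain +
batch` fitted to all genes through one QR decomposition. On the linear-model
path the residual variances are shrunk toward a common prior by empirical
Bayes (`limma::squeezeVar`); with ~6 replicates per arm the unmoderated
per-gene variance estimate is the dominant noise source, and moderation is
what every log-scale DE tool in this field does. `moderate = FALSE`
restores plain per-gene statistics. Significance is gated on BH q < 0.01
with no fold-change cutoff. Negative-binomial GLM shrinkage is deliberately
out of scope; `import_external_de` is the fidelity path for substituting a
dedicated count-model tool's output.

# The synthetic cohort and what it does (not) emulate

The generator produces a complete in-silico study: 9 mutant strains with
longevity effects spanning 26%–138% (the published panel's spread), matched
wild-type controls (including the 25°C-reared control for the
temperature-sensitive strain), 120 worms per assay arm in 3 biological
replicates, 6 RNA-seq replicates per strain with 2 batches, and ~5% uniform
censoring.

* **Death times** are Weibull with shape 3 (sigmoidal survival curves like
  real worm assays; exponential hazards would be unrealistically flat). Raw
  worm survival-time distributions are rarely published; the Weibull is a
  stand-in, not a claim about any dataset. Mean survival scales linearly
  with the Weibull scale, so configured longevity effects are recovered
  exactly in expectation at any shape.
* **Strain stress traits** mix a shared robustness factor (equal to the
  longevity effect) with stressor-specific factors:
  `t_a = w_a·L + (1−w_a)·A_a`, with `A_a` uniform on `[−span, span]` so a
  long-lived strain can still show *decreased* resistance to an individual
  stressor, as real panels do. Default weights are high (0.9; 0.95 for the
  pathogen analog, which tracks longevity most closely); per-assay coupling
  strengths are graded so that, at default power, nearly every strain shows
  detectable heat and pathogen resistance while only the longest-lived show
  anoxia resistance — reproducing the published per-assay pattern and
  making the resistance count a graded, monotone correlate of longevity.
* **Counts** follow `mean = baseline · 2^(β·driver + batch)` with negative
  binomial dispersion 0.1 (Poisson below 1e-12), baselines lognormal
  (median 200), and per-gene batch shifts (sd 0.2 log2 units) for batches
  beyond the first. Gene modules: `shared_driver` genes read the mean
  stress trait, `lifespan_only` genes the longevity effect,
  `stress_specific:<assay>` genes their assay's trait, `null` genes nothing.
  Coupling signs are negative for 30% of planted genes.
* **Determinism**: every randomized arm draws from a stream seeded by a hash
  of the master seed and the arm's identity (strain, assay, replicate), so
  outputs are byte-identical across runs and independent of generation
  order.

What the generator does **not** emulate: read-level sequencing artifacts,
gene–gene correlation beyond the planted modules, library-composition biases
beyond global size factors, trial-day effects in survival assays, secular
drift between batches of worms, or the pharynx/feeding mechanics that make
the dietary-restriction mutant pathogen-sensitive. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under a
plausible data-generating process — not that any particular biological
conclusion transfers to real data.

# Validation strategy and problem sizes

The published headline numbers depend on raw assay measurements shown only
in figures and on deposited RNA-seq data, so validation is property-based:

* **Type-I calibration**: log-rank, Gehan–Wilcoxon, Welch t and
  family-wise Dunnett each within the binomial 95% interval of α = 0.05
  over 2000 null simulations at 40 animals per arm.
* **Oracle equivalence**: hypergeometric p vs 10^5 random-set draws;
  log-rank chi-square p vs 10^4 label permutations; restricted mean vs the
  hand-computed step-function area.
* **Null enrichment**: mean O/E ratio over 10^4 random set pairs within
  [0.98, 1.02]; significant fraction bounded near α.
* **Parameter recovery**: a 10-strain, 6-replicate, 5000-gene cohort with
  200 planted shared drivers at 1 log2-unit coupling and dispersion 0.1;
  recovery uses the q-gated rule at 0.1 (a raw-p rule cannot keep the
  false-discovery proportion at these planted proportions). Sensitivity
  ≥ 0.8 and FDP ≤ 0.2; the stress-positive vs lifespan-positive overlap is
  strongly enriched under fully shared coupling, and null cohorts (no gene
  coupling, stress traits independent of longevity) give O/E ratios whose
  confidence interval covers 1.
* **Count–longevity regression**: evaluated over 5 replicate cohorts with
  Fisher-combined one-sided slope p-values; with 9 strains and six
  near-binary calls a single cohort has irreducible count noise, so the
  replicate-cohort combination is the stable statement of the property.
* **Worked example**: a bundled reference panel of the nine published
  mutants (lifespan extensions and per-stressor direction calls compiled
  from the published per-assay outcomes) reproduces a strong positive
  resistance-count regression. The published summary table draws on
  supplementary time points not available here, so individual calls — and
  hence the exact printed R² — can differ from it; the corresponding
  acceptance check documents this gap rather than papering over it.

# Known limitations

* The Gehan test uses the chi-square approximation; exact permutation is
  available only indirectly (the suite demonstrates agreement for the
  log-rank case).
* The DE stage models log-transformed counts, not counts; genes with very
  low counts are under-powered relative to an NB-GLM with shared dispersion
  estimation.
* Dunnett assumes homogeneous variances; strongly heteroscedastic replicate
  proportions (endpoints near 0 or 1) would call for a transformation the
  package does not apply.
* Expression–phenotype correlation treats strains as independent draws; it
  ignores shared genetic background or batch confounding beyond the
  balanced design the generator produces.

# A minimal session

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- generate_cohort(cfg)
dir <- tempfile()
paths <- write_cohort(cohort, dir)

res <- run_all(run_config(
  survival_path = paths[["survival"]],
  counts_path = paths[["counts"]],
  metadata_path = paths[["metadata"]],
  pathway_gmt = paths[["gene_sets"]],
  assays = cfg$assays,
  out_dir = file.path(dir, "out")
))

res$phenotypes              # strain table: extension, scores, counts
res$regressions             # phenotype-vs-lifespan fits
res$stress_lifespan_overlap # observed/expected overlap per stressor
```
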