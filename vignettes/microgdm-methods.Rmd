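---
title: "microgdm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{microgdm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgdm)
```

# What this package does

`microgdm` re-implements, as one tested pipeline, the gut-microbiome
case-control analysis used to characterize and predict gestational diabetes
mellitus (GDM) from early-pregnancy stool 16S profiles: rare-OTU filtering,
rarefaction, taxonomic aggregation, seven alpha-diversity indices with
two-group Welch t-tests, four beta-diversity distances with PCoA and
PERMANOVA, LEfSe-style differential-abundance effect sizes, SparCC
compositional correlation networks, Spearman correlation of differential
genera with clinical indices, and a forward-selection linear-discriminant
(LDA) classifier with leave-one-out cross-validation (LOOCV), ROC/AUC with
DeLong confidence intervals, and frozen-model external validation.

The deposited cohort behind the original study is not redistributable, so
the package ships a synthetic-cohort generator with known ground truth.
Everything downstream is exercised, and its statistical behaviour verified,
against that generator.

# The synthetic cohort: a stated world

`cohort_config()` describes a nested case-control design: 98 matched
case-control pairs, split 70 pairs into a discovery set and 28 into a
validation set, mirroring the replicated study's 70/70 + 28/28 layout.

**Abundance model.** Genus `g` has baseline log abundance
`mu_g = -0.08 * g`, a geometric rank-abundance backbone giving a dominant
genus near 8% relative abundance and a long rare tail — the shape of a
typical stool genus table. Per-sample latent log abundances add (i) a
per-pair, per-genus shift `N(0, 0.3)` shared by the two members of a
matched pair (matching on age/gestational age/collection date induces
exactly this kind of shared environmental variance), (ii) a group effect
`+-log(2) * log2fc` on the spiked genera, and (iii) independent noise
`N(0, 0.9)`. Latents are soft-maxed to a composition; reads are multinomial
at a log-normal depth with mean 63,218 (the study's mean depth) and
log-SD 0.25. Defaults spike 3 case-enriched and 9 control-enriched genera
at a 2-fold change — the direction split of the study's differential-genus
figure — at moderately abundant ranks (0.3-4% relative abundance), because
that is where reported GDM-associated genera live. All of these values were
fixed before the acceptance measurements and are config fields, not dials.

**Clinical block.** Each index is Gaussian per group; defaults approximate
the published cohort's early-pregnancy table (fasting glucose 4.63 vs 4.89
mmol/L; GGT, BMI, SBP/DBP, triglycerides, fasting insulin, hsCRP). The
published table reports medians/IQRs for the skewed indices; we use
moment-matched Gaussians and do not claim to match the real joint
distribution.

**Taxon-clinical coupling.** Target Spearman correlations (defaults in the
reported 0.17-0.23 band) are imposed by a Gaussian copula on ranks. A
subtlety: when both the genus and the index carry a case/control mean
shift, the shift itself contributes correlation. The loading is therefore
solved from

```
rho_P * sd(c) = s_bar * b * sqrt(1 - a^2) + a * dm / 2
```

where `rho_P = 2 sin(pi rho_S / 6)` is the latent Pearson target, `a` the
genus's standardized half-shift, `dm` the index's case-control mean
difference and `s_bar` its average within-group SD; `b` then multiplies the
genus's *within-group* normal-score residual, which preserves the group
marginals exactly. With the naive loading the realized correlations
overshoot their targets by up to 0.15; with this correction the 12-seed
mean is within 0.02 of every target.

**What the generator does not emulate.** Sequencing error, chimeras,
zero-inflation beyond the multinomial, longitudinal structure, and
non-Gaussian clinical tails. A green test therefore establishes that the
statistics behave correctly under a realistic compositional log-normal
world — not that the original cohort's values are reproduced.

# Ground-truth discriminability

`estimate_bayes_auc()` answers "how predictable is GDM in this simulated
world?". It draws two large independent cohorts from the full generative
model (including read noise), fits the group-conditional Gaussian
likelihood ratio on the signal block — log10 relative abundances of the
spiked genera (pseudo-fraction `1e-6`) plus the clinical indices — on the
first draw, and reports its AUC on the second. Because the two groups have
different clinical SDs, this likelihood ratio is *quadratic*; it is the
Bayes ceiling for the observable signal block.

This creates a documented tension with the prediction exercise: the
replicated study's classifier family is linear, while unequal group SDs in
the clinical block make the Bayes frontier quadratic. In the replica world
(5 control-enriched genera at log2FC 0.8 + fasting glucose + GGT
informative) the quadratic ceiling is ~0.87, the best *linear*
discriminant attains ~0.83 asymptotically, and the greedy
forward-selection model's median validation AUC across seeds is ~0.82 —
inside the acceptance band of 0.05 around the ceiling, but structurally
close to its edge. The remaining gap is the family mismatch plus selection
optimism, not an implementation defect; both components are measured by
the test suite rather than asserted.

# Parameter conventions

* **Filtering** removes features with total count strictly below 0.005% of
  the grand total (the study's rule; boundary counts are kept).
* **Rarefaction** subsamples without replacement to exactly 36,000 reads;
  shallower samples are dropped, never scaled.
* **Alpha diversity**: Shannon in bits and Heip's evenness
  `(2^H - 1)/(S - 1)`, matching the convention of the toolkit named in the
  study's methods; Chao1 uses the classic `S + F1^2/(2 F2)` form, switching
  to the bias-corrected form only when `F2 = 0` (avoids division by zero
  without abandoning the classic estimator); ACE uses the standard
  rare/abundant cut at 10 reads and is flagged `NA` when the rare-class
  coverage is zero.
* **Beta diversity**: Jaccard on presence/absence, Bray-Curtis on counts
  (the standard pairing; the study does not say), UniFrac by branch-wise
  accumulation on the supplied rooted tree; weighted UniFrac defaults to
  the raw form with the normalized (`[0,1]`) variant behind a flag. The
  tree is always an input — the study does not state how its tree was
  built, and the package never infers one.
* **PERMANOVA** permutes labels freely by default (the study analyzed the
  sets unmatched); a within-pair stratified mode exists. The permutation p
  includes the observed statistic in numerator and denominator, so
  `p >= 1/(n_permutations + 1)`.
* **LEfSe**: two classes only (the study defines no subclasses, so the
  original procedure's subclass stage collapses away); per-million scaling
  before the discriminant, which is what makes the score cutoff of 2
  meaningful; ridge `1e-6 * trace` on the pooled covariance because
  compositional tables are collinear; scores floored at `log10(1) = 0`.
  The exact internal constants of the original tool are not published in
  the replicated study; the implementation is validated behaviourally
  (spike recovery, null calibration) rather than against binaries.
* **SparCC**: pseudocount 1 inside the Dirichlet resampling, 20 exclusion
  iterations at threshold 0.1, 20 resamples, 100 permutation bootstraps —
  the algorithm's conventional settings, since the study states none. Edge
  rules `|rho| >= 0.3`, `p < 0.05` are config defaults; the study's own
  thresholds are unstated.
* **Classifier**: genus candidates are log10 relative abundances
  (pseudo-fraction `1e-6`) of genera present in >= 10% of discovery
  samples; "performance" in the selection loop is LOOCV AUC with accuracy
  as tie-break (the study reports AUC as its headline metric; an
  accuracy-first mode is a flag); the final model is the trajectory prefix
  with the best LOOCV performance; CIs are DeLong; the operating threshold
  is the Youden point on discovery scores, frozen for validation.
  `max_features` defaults to 10 (the study's model used 7).

# Numerical notes and degenerate inputs

* LDA is fitted on internally standardized features with ridge
  `1e-6 * trace(S)`; exact collinearity (duplicated columns) is an error in
  the classifier path and ridge-absorbed in the effect-size bootstrap.
* LOOCV downdates the class means and scatter per fold (exact, O(n d^2));
  LDA scores are invariant to the global standardization, so no information
  leaks across folds. Pooled LOOCV scores of a *null* feature are
  intrinsically high-variance (the fitted direction flips sign between
  folds), which is why null LOOCV AUC is tested on its mean across seeds.
* PCoA reports negative eigenvalues but excludes their axes; proportions
  explained are relative to the positive-eigenvalue total.
* Kruskal-Wallis on an all-tied vector returns `p = 1` by convention;
  Spearman on a constant vector is flagged `NA`, never coerced to 0.
* All randomized stages take explicit seeds; the pipeline fans one global
  seed out per stage by hashing the stage name (`derive_seed()`), keeping
  every derived seed below 2^31.

# Known limitations

The LOOCV-based greedy selection inherits the original procedure's
selection bias (no nested CV) — deliberately, as that is the procedure
being replicated. The SparCC null floor at n = 200 samples is the sampling
noise of any correlation estimator (~0.057 mean absolute), so "null
correlations ~ 0.05" is only attainable at larger n. Pathway-level
analysis is supported generically (any feature table can be fed to
`lefse()` / `correlation_grid()`), but functional prediction itself is out
of scope.
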