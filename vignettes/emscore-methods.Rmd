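---
title: "Expression modifier scores and functionally informed fine-mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression modifier scores and functionally informed fine-mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emscore)
```

## The problem

Statistical fine-mapping of cis-eQTLs assigns each variant–gene pair a
posterior inclusion probability (PIP) of being causal for the gene's
expression, but in regions of strong linkage disequilibrium (LD) the
association data alone cannot distinguish tightly correlated variants: an
effect shared by four variants in perfect LD yields PIP = 0.25 for each.
Functional annotations — distance to the transcription start site (TSS),
chromatin peaks, sequence-based activity predictors — carry exactly the
information LD hides. `emscore` implements a two-stage strategy:

1. **The expression modifier score (EMS).** A random-forest classifier is
   trained to distinguish confidently fine-mapped causal pairs from
   confidently null pairs using functional features only, and its output is
   calibrated into an estimated probability that a variant–gene pair is a
   putative causal eQTL.
2. **Approximate functionally informed fine-mapping.** The EMS is used as a
   prior to reweight the per-effect posteriors of a sum-of-single-effects
   fine-mapping model, yielding a functionally informed posterior
   (`PIP_EMS`) without re-running the fine-mapper.

Downstream, the package provides colocalization with complex-trait
fine-mapping results (CLPP), enrichment statistics, and tissue-specific
putative causal eQTL analysis.

## Labels and features

Training labels come from two independent fine-mapping methods: a pair is
**positive** when both methods give PIP > 0.9, **negative** when both give
PIP < 1e-4, and unlabeled otherwise (`construct_labels()`; thresholds are
arguments). On synthetic data the package's own fitter supplies both PIP
columns, so the two-method concordance rule degenerates to a single-method
rule there — a limitation of the synthetic setting, not of the code path.

Features are assembled by `build_feature_matrix()` from three sources, with
coordinate conventions handled only at the I/O boundary (variant tables are
1-based inclusive, BED is 0-based half-open):

- **distance**: signed bp from variant to TSS, sign flipped on minus-strand
  genes so positive is always downstream of transcription;
- **binary**: 1 iff the variant position falls inside at least one interval
  of a named BED set (only the position is used — allele-aware scores must
  arrive precomputed as continuous columns);
- **continuous**: numeric columns joined by variant or by pair, the
  per-pair value winning where both exist; missing entries are filled with
  0 (absence of a score is treated as absence of activity) and the fill
  count is reported.

## Classifier and calibration

Training is leave-one-chromosome-out (`train_ems()`): the model that scores
a chromosome has never seen it. Within the training partition, classes are
balanced (all positives plus an equal-size seeded negative sample), the top
`k` features are selected by mean decrease of impurity from a preliminary
forest (default `k = 152`, ties broken lexicographically), and
hyperparameters (`mtry`, `min.node.size`) are tuned by random search plus a
small local grid, maximizing AUROC on a stratified validation split;
`search_budget = 1` skips the search.

Raw forest probabilities are not probabilities of the genome-wide event of
interest: the training mix is balanced while true causal pairs are rare.
`calibrate_to_ems()` therefore cuts held-out raw scores into quantile bins
(default 20, computed on the distinct score values so that heavy ties at a
single score cannot swallow the range; adjacent bins with fewer than 50
labeled pairs are merged; a fully degenerate constant score collapses to
one all-covering bin), computes the positive fraction $f$ per bin, and
rescales it from the training prevalence $\pi_t$ to the genome-wide base
rate $\pi$ by prior odds:

$$\mathrm{EMS} = \frac{f\,\pi/\pi_t}{f\,\pi/\pi_t + (1-f)(1-\pi)/(1-\pi_t)}$$

The simpler reading — use $f$ directly — is available with
`rescale = FALSE`. The default $\pi$ is the positive fraction over all
input pairs, overridable. Finally the per-bin values are made non-decreasing
in raw score by pooling adjacent violators weighted by bin size, so EMS is
monotone in the classifier output.

For episomal-assay settings, where the native genomic TSS distance is
meaningless, `score_pairs(..., fixed_tss_bp = 200)` overrides the distance
feature with a constant before scoring.

## The sum-of-single-effects fitter

`ibss_fit()` fits the model $y = Xb + \varepsilon$ with
$b = \sum_{l=1}^{L} b_l$, each $b_l$ having exactly one nonzero entry, by
iterative Bayesian stepwise selection: each sweep refits every single
effect against the residual of all the others, producing per-effect
posterior probability vectors $\alpha_l$ over variants. Numerical choices:

- columns standardized and phenotype centered internally; constant columns
  are an error;
- per-effect prior effect variance chosen by marginal likelihood on a fixed
  grid of fractions of $\mathrm{var}(y)$ including exactly zero — an effect
  whose prior variance shrinks to zero is *inactive*: it contributes no
  credible set and is excluded from PIPs;
- residual variance re-estimated each sweep from the expected residual sum
  of squares;
- convergence when the evidence lower bound changes by less than `1e-6`,
  at most 200 sweeps; hitting the cap flags the fit rather than failing.

PIPs combine retained effects as
$\mathrm{PIP}(v) = 1 - \prod_l (1 - \alpha_l(v))$. The 95% credible set of
an effect is the smallest prefix of variants in descending $\alpha$ (ties
broken by ascending variant id) reaching 0.95 cumulative mass. A set is
**pure** iff the minimum absolute pairwise correlation among its members is
at least 0.5, computed on the sample genotype correlation of the analyzed
cohort (no external LD panel); singletons are pure by convention.

## Reweighting

For each effect whose credible set is pure,

$$\hat\alpha_l(v) = \frac{w_v\,\alpha_l(v)}{\sum_u w_u\,\alpha_l(u)},$$

with $w$ the per-variant EMS; impure effects pass through unchanged
(`reweight_alpha()`). The reweighting is invariant to rescaling of $w$,
uniform weights are an identity, and the variant with the largest weight
never loses posterior mass. Updated PIPs and credible sets are computed
from $\hat\alpha$; eligibility for reweighting is decided by the
uniform-prior purity, as the procedure orders the steps. Variants without a
score receive the 5th percentile of the supplied weights, so unscored
variants are down- but not zero-weighted. An optional prior-ratio cap
(`adjust_prior_ratio()`, default ratio 100) floors the weights at
`max(w)/100`; a floor rather than a ceiling preserves the top of the prior.

```{r cited4}
ex <- run_cited4_example()
round(ex$pip_ems, 4)
c(clpp_informed = ex$clpp_ems$clpp, clpp_uniform = ex$clpp_unif$clpp)
```

The bundled worked example (`cited4_fixture()`) is the canonical
illustration: four variants in perfect LD share a single effect at
$\alpha = 0.25$ each; their EMS values span two orders of magnitude; after
reweighting the lead variant reaches PIP 0.956 and the gene's
colocalization with a blood-trait signal crosses the 0.1 threshold
(CLPP 0.173) that the uniform posterior (max CLPP 0.045) cannot reach.

## Evaluation machinery

`enrichment()` computes $P(\text{set}\mid\text{bin}) / P(\text{set})$ with
a binomial standard error on the numerator proportion divided by the
denominator; the denominator is treated as fixed, appropriate when the
total count is large. Over any full partition of bins the mass-weighted
mean enrichment is exactly 1. `percentile_bins()` cuts scores at
percentile edges of their own distribution (default deciles plus a finer
99th-percentile top bin), right-closed, with ties always sharing a bin.
`downsample_keep_set()` keeps the whole set of interest and samples
non-set rows to a fixed total (default 100,000). `score_eval()` reports
AUROC (threshold sweep) and AUPRC (average precision by step summation).

`clpp()` takes the maximum over tissues and credible-set variants of the
product of eQTL PIP and trait PIP; `prioritize_genes()` requires
CLPP > 0.1 *and* the strict regional maximum — a tie at the maximum
prioritizes nothing, a deliberate conservative choice. Precision is
correct/prioritized (undefined when nothing is prioritized), recall is
correct/evaluation-genes.

Tissue-specific putative causal eQTLs have PIP > 0.9 in one tissue and
< 0.1 (or missing — missingness is treated as low) in every other. A
transcription factor is specific to the tissue with the unique maximum TPM
when that maximum exceeds the across-tissue mean (including the candidate
tissue itself) by more than two sample standard deviations; control tissues
are those below a tenth of the maximum, and a call without controls is
dropped. The enrichment test is a two-sided Welch t test at a Bonferroni
level of 0.05 divided by the number of features tested; Welch rather than
pooled variance because the two groups of eQTLs have no reason to share a
variance.

## The synthetic-data generator

The generator (`simulate_catalog()` and friends) produces data with the
statistical structure the method assumes, so every stage is testable
without external data:

- **genotypes**: Gaussian-copula haplotypes thresholded at allele-frequency
  quantiles (Hardy–Weinberg dosages), in LD blocks with within-block latent
  correlation `rho` and independence across blocks. MAF is drawn per block
  — tightly linked variants share allele frequencies, and equal thresholds
  keep the dosage correlation close to `rho`;
- **causality**: either a per-variant Bernoulli rate or, with
  `causal_mode = "block"`, a fixed fraction of LD blocks carrying one
  causal variant each, mirroring the small number of independent signals at
  real eQTL loci;
- **expression**: standardized genotypes times normal effects plus
  Gaussian noise;
- **features**: causal pairs sit nearer the TSS (two-sided exponential,
  default scale 10 kb; non-causal uniform over the ±1 Mb cis window),
  binary peak features fire 10-fold more often in causal pairs over a 2%
  base rate, and continuous scores are the standardized causal indicator
  times an informativeness coefficient plus unit noise;
- **trait**: an optional complex trait shares the causal variants of a
  subset of genes; its PIPs come from running the bundled fine-mapper on
  the simulated trait, not from a formula, so colocalization tests exercise
  the real code path.

All randomness flows from one integer seed through a documented
hierarchical split (`derive_seed()`), and fixed seeds reproduce
byte-identical outputs.

What the generator does **not** emulate: realistic allele-frequency
spectra, recombination maps, population structure, allele-aware functional
scores, or the correlation structure of thousands of real annotation
tracks. Passing tests on synthetic data therefore demonstrate correctness
of the algorithms and calibration under the stated generative model, not
performance on real cohorts.

## Problem sizes and defaults in the test suite

The package's own evaluation uses sizes chosen to make every property
measurable with stable statistics: the recovery benchmark simulates 300
genes with 200 variants each (blocks of 10 at `rho = 0.9`), 400
individuals, 10% of blocks causal with per-variant effects of standard
deviation 0.3 (about 4–9% expression variance each, in the range of strong
cis effects), over three seeds. On it, the informed posterior recovers at
least as many true causal variants at PIP > 0.9 as the uniform posterior,
with empirical FDR at or below 0.1, and pure credible sets never grow. The
calibration check trains on 40,000 pairs at a 5% positive rate and verifies
that per-bin mean EMS lies within the 95% binomial interval of the held-out
positive rate for every bin with at least 200 pairs. The demonstration
pipeline (`run_pipeline()`) uses 18 genes of 40 variants so that it runs in
seconds; at that scale the calibration table is coarse and EMS can collapse
to few distinct values, which the pipeline reports rather than hides.

## Known limitations

- The bundled fitter is a lightweight reference implementation: it assumes
  a single cohort, complete genotypes, and quantitative phenotypes, and
  estimates purity from the sample correlation matrix only.
- On synthetic data the two fine-mapping methods of the labeling rule are
  the same fitter; concordance filtering does not reduce noise there.
- The calibration is binwise-constant: EMS takes at most as many values as
  there are calibration bins, which at small scales is visible as ties.
- The exact rescaling behind the published score calibration is not fully
  specified; both the prior-odds rescaling (default) and the raw positive
  fraction (`rescale = FALSE`) are provided.
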