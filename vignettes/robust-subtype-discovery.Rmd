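---
title: "Robust binary subtype discovery and validation with risisr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust binary subtype discovery and validation with risisr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bulk expression profiles of high-grade serous ovarian tumors show no single
obvious clustering; the question is whether reproducible *binary* molecular
subtypes exist at all, and if so, whether they can be carried to other
cohorts measured on other platforms. `risisr` implements a complete workflow
for that question:

1. **Discovery** — an ISIS-style search for binary sample partitions, each
   supported by a dedicated gene module, with a permutation test that allows
   the honest answer "there is no subtype here".
2. **Stability selection** — the robust layer: the search is repeated on
   random subsets of the training samples, classifiers trained on each
   rediscovered partition predict the held-out samples, and only partitions
   whose predictions are consistent in more than 95% of the evaluations are
   retained, first in the training set and then on an untouched
   model-selection set.
3. **Cross-omics confirmation** — a nearest-shrunken-centroid (PAM)
   classifier with nested cross-validation tests whether microRNA profiles
   of the same tumors predict each partition.
4. **A portable score** — the first partition's discriminant weights turn
   any expression matrix into one score per sample in $[-1, 1]$; a
   Gaussian-mixture/BIC analysis decides whether the score distribution is
   genuinely bimodal before any sample is called *angiogenic* or
   *non-angiogenic*.
5. **Clinical anchoring** — Kaplan–Meier/logrank, Cox hazard ratios and
   Fisher tests associate the calls with survival, grade, stage and
   debulking.

Because the original tumor data cannot be bundled, the package ships a
synthetic-cohort generator that reproduces the *structure* of such a study,
and every stage is exercised against it.

## The discovery model

For a candidate bipartition $L$ of the samples into classes $g_0$ and $g_1$
($|g_1| \le |g_0|$), every gene $g$ receives a pooled-variance two-sample
$t$ statistic with an additive variance floor:

$$ t_g = \frac{\bar x_{g,1} - \bar x_{g,0}}
      {\sqrt{(s^2_{p,g} + s_0)\,(1/n_0 + 1/n_1)}}, $$

where $s_0$ is the median per-gene variance of the matrix. The module
$M(L)$ is the $m$ genes with largest $|t_g|$ (default $m = 100$) and the
split score is

$$ S(L) = \frac{1}{m} \sum_{g \in M(L)} t_g^2 . $$

$S$ is symmetric in the two classes and invariant to gene and sample order.
The variance floor keeps near-constant genes from dominating through tiny
denominators; choosing the median variance makes the floor scale with the
data rather than an absolute constant.

**Candidate generation.** Seeds come from two families: 2-means clusterings
of each of the top 10 principal components, and largest-gap threshold
splits of the 200 most variable genes. Each seed is refined by greedy
single-sample reassignment — flip the sample whose move increases $S$ —
until a fixed point, capped at 50 sweeps. On 8-sample matrices with
exhaustive single-gene threshold seeding the refined optimum matches a
brute-force enumeration of all bipartitions (this is a test in the suite).

**Significance.** Permuting whole columns leaves an unsupervised score
unchanged, so the null is built by permuting each gene's values across
samples *independently*, which preserves every gene's marginal distribution
while destroying the gene–sample association that a real subtype induces.
For each of `n_perm` (default 100) draws the *entire* seeded search is
re-run on the permuted matrix and the maximum refined score is recorded;
a candidate's p-value is the fraction of null maxima reaching its score
(with the usual +1 correction). Taking the maximum per draw accounts for
selection over the many candidates the search considers. Candidates with
$p \ge \alpha$ (default 0.05) are discarded; surviving splits agreeing more
than `redundancy_max` (default 0.8, after optimal class matching) are
collapsed to the higher-scoring one. An empty result is a legitimate
outcome, not an error.

**Minimum class size** defaults to $\max(5, 0.1\,n)$: minority classes
near a quarter of the cohort — the size at which binary tumor subtypes are
typically reported — must remain discoverable, while splits peeling off a
couple of outlier samples are excluded.

## Bootstrap stability

Each replicate draws $\lfloor 0.63\,n \rfloor$ samples without replacement
(the expected fraction of distinct samples in a with-replacement bootstrap;
both the fraction and the number of replicates, default 100, are
parameters — the procedure's reference description fixes neither). The
search is re-run on the subset; a rediscovered split is matched to a base
split when their label agreement on the shared samples reaches 0.75 after
class matching. A diagonal linear discriminant trained on the matched
replicate split then predicts the replicate's held-out samples, and the
agreement between those predictions and the base split's labels (with the
orientation fixed by the matching step, so chance-level predictions are not
flattered) is averaged over matched replicates. Replicates in which the
search returns nothing count against the reported `matched_fraction` but do
not dilute the stability mean — a split should be judged on the replicates
that could see it.

Retention uses a strict inequality at the 0.95 bar. With
`train_fraction = 1` there is nothing held out; in-sample predictions are
used, so an exactly rediscoverable split has stability 1.

Inside the bootstrap the permutation filter is off by default
(`n_perm = 0`): significance has already been established on the full
training data, and the matching step is the gate that decides which
replicates contribute.

**Holdout confirmation** is deliberately symmetric with the training-side
machinery: the full-training classifier predicts the model-selection
samples, those predictions define a base split on the holdout matrix, and
the same bootstrap-stability procedure is run there. A real split yields
consistent holdout predictions; a corrupted or noise split either predicts
a near-degenerate partition (rejected outright) or one that the holdout
search cannot rediscover (never matched, hence unstable).

## PAM with nested cross-validation

The nearest-shrunken-centroid classifier uses the standard soft-threshold
formulation: standardized class-versus-overall centroid differences
$d_{kg} = (\bar x_{kg} - \bar x_g) / (m_k (s_g + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, shrunken by
$d'_{kg} = \mathrm{sign}(d_{kg}) \max(0, |d_{kg}| - \Delta)$. Class priors
are the empirical proportions — the asymmetric per-class error rates this
produces on imbalanced splits are intended, matching how such confusion
tables are reported. Outer folds (default 10, stratified) give the unbiased
error estimate; inner folds (default 5) choose $\Delta$ from 30 evenly
spaced values between 0 and $\max |d_{kg}|$, with ties resolved toward the
larger (sparser) value. Consensus features are the strict intersection of
the surviving features across all outer-fold models. Fold counts and the
grid are package defaults; the reference workflow does not state its own.

## The subtype score

Expression is first robustly scaled per gene: values are clipped at the
2.5% and 97.5% quantiles and those quantiles mapped affinely to $-1$ and
$+1$. Quantile clipping is insensitive to outliers and equivariant under
positive affine transforms, which is what makes the score portable across
platforms with different dynamic ranges; "robust scaling" admits many
implementations and this one was chosen for exactly that property.
Constant genes map to 0 and contribute nothing. The score of sample $s$ is

$$ \mathrm{score}_s = \frac{\sum_g w_g x_{gs}}{\sum_g |w_g|} \in [-1, 1], $$

with weights $w_g = (\bar x_{g,1} - \bar x_{g,0})/(s^2_g + s_0)$ from the
split-1 discriminant (positive = higher in the angiogenic class). Signature
genes missing from a new platform are dropped from both sums, so partial
gene overlap degrades the score gracefully rather than biasing it.

Whether the cohort *has* two subtypes is decided before any call is made:
univariate Gaussian mixtures with $k = 1 \dots 5$ components are fitted by
EM (k-means initialization, 5 restarts, tolerance $10^{-6}$, a relative
variance floor of $10^{-6}$ against component collapse) and compared by
$\mathrm{BIC} = -2\ell + (3k - 1)\ln n$, minimized. If $k = 1$ wins, a
no-subtype flag is returned instead of calls. Otherwise the component with
the highest mean is the angiogenic one; a sample is called angiogenic when
its posterior probability for that component exceeds one half, and the
score at which the posterior crosses 0.5 (found between the two top
component means) is reported as the decision boundary.

## Survival and clinical statistics

Kaplan–Meier curves, the two-sample logrank test and the Cox model are
delegated to the `survival` package, with Efron tie handling — the better
small-sample convention, chosen because the reference analysis does not
state its software's default. Wald 95% intervals are
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$. Complete separation (monotone
likelihood) is detected and surfaced as a warning rather than a silent
huge coefficient. Fisher tests use the exact two-sided probability-mass
rule for 2×2 tables and seeded Monte Carlo with the $(k+1)/(B+1)$
correction for larger tables; zero-margin rows and columns are dropped
with a warning. Subtype proportions are reported as integer-rounded
percentages, the convention of the clinical tables they mirror.

## Enrichment

Functional characterization of a module is over-representation against
user-supplied GMT gene sets: hypergeometric upper-tail p-values with
Benjamini–Hochberg FDR control, flagged at 10%. A fixed 100-gene module
makes set overlap the natural statistic; rank-based GSEA variants depend
on an annotation snapshot and a weighting scheme and are intentionally out
of scope.

## What the synthetic generator emulates — and what it does not

`cohort_spec()` defaults describe the emulated study: 129 tumor samples on
a log2-like intensity scale (gene baselines $\mu_g \sim N(8, 1.5^2)$),
~12,000 genes, twelve samples assayed in duplicate, four planted binary
partitions each carried by a disjoint 100-gene module, 743 microRNAs with
a subset tracking the first partition, exponential survival with a
subtype-dependent hazard (default HR 1.3 for the minority class), ~30%
uniform censoring, and categorical grade/stage/debulking covariates drawn
from fixed frequencies (optionally tilted by a log odds-ratio to create a
real association). Duplicates are appended as extra suffixed columns with
an explicit pair table — the duplicate-variability filter needs both
copies, so averaging them away would remove the very information it uses.
The minority fractions of the four default splits (0.26–0.41) bracket the
class sizes reported for such cohorts, and all four share the same effect
size (2.5 noise SDs); the first split is made the *best supported* one
through the microRNA layer rather than through a larger mRNA effect, since
the reference gives no effect-size scale to copy.

The generator deliberately omits batch effects, probe-level artifacts,
correlated gene–gene noise within modules, copy-number or mutation layers,
and platform-specific intensity distributions. Passing tests therefore
demonstrate that the machinery recovers structure of the assumed form at
realistic sizes and noise levels — not that real tumor cohorts contain
such structure, nor that the pipeline is robust to artifacts it never
sees.

## Numerical and design choices

* **Sequential filtering**: the duplicate-variability criterion (mean
  absolute within-pair difference above the 0.75 quantile excludes a gene)
  is applied before the top-$k$ variance ranking, and variance is computed
  with second copies excluded so technical replicates are not double
  counted. Ties in the variance ranking break by gene ID, making the
  filter order-invariant.
* **Equal-error threshold**: the discriminant's decision threshold sits
  where the two training error rates are closest (ties: smaller total
  error, then smaller threshold), rather than at zero — robust to
  imbalanced classes.
* **Missing signature genes at prediction time** drop out with the
  projection rescaled by the ratio of total to available absolute weight,
  keeping projections comparable with the trained threshold.
* **Deterministic tie-breaks everywhere**: lexicographically first class
  on PAM score ties, larger $\Delta$ on inner-CV ties, gene-ID order on
  ranking ties, canonical class orientation (the smaller class is `g1`).
* **Seeding discipline**: one user-visible seed per entry point; internal
  stages derive sub-seeds by a fixed linear rule, so whole-pipeline runs
  are byte-reproducible (`run_pipeline` writes identical artifacts for
  identical configurations).
* **Problem sizes in the test suite**: discovery-with-null checks run at
  the full emulated scale (12,000 genes, 129 samples, 82-sample training
  set) once; the pure-noise calibration uses twenty 250-gene × 40-sample
  cohorts and the remaining property checks use cohorts of 20–120 samples
  — sizes chosen so the suite exercises every claim at meaningful power
  while remaining routinely runnable on a laptop.

## Known limitations

* The split-score surrogate preserves the published contract (diagonal
  LDA on the 100 most significant genes) but is not claimed to match the
  original ISIS score numerically; the original's candidate generation is
  likewise documented only by reference.
* Only binary partitions are searched; cohorts with more complex
  substructure will surface as several overlapping binary splits or as
  unstable candidates, not as a $k$-way clustering.
* The permutation null destroys gene–gene correlation, so heavily
  co-regulated but subtype-free data (e.g. strong batch structure) can
  yield optimistic significance; the stability layer is the intended
  backstop.
* Monte Carlo Fisher p-values carry simulation error of order
  $1/\sqrt{B}$; the default $B = 10^5$ makes that ~0.003.
* With a single mixture component (no bimodality) the score stage refuses
  to call subtypes; it does not attempt to rescue weak separation by
  lowering the bar.
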