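---
title: "Methods: archetypes, topics and cellular deconvolution for continuous tumor heterogeneity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archetypes, topics and cellular deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bulk tumor transcriptomes rarely fall into discrete clusters. In cohorts such
as blastemal-type Wilms' tumors, samples spread continuously between a few
extreme expression states — stromal, epithelial and blastemal — so any hard
clustering misrepresents them. `tricontinuum` characterizes such continuous
heterogeneity from three independent angles and checks that they tell the
same story:

1. **Archetypes** (Pareto task inference): samples occupy a low-dimensional
   polytope in PCA space; its vertices are idealized extreme tumors.
2. **Topics** (grade of membership): each sample is a probabilistic mixture
   of k latent gene-expression programs.
3. **Cellular deconvolution**: each sample is a weighted sum of single-cell
   reference profiles, summarized as cell-type proportions.

All three decompose a sample into k non-negative components that sum to a
whole; on a cohort truly generated from k latent components they must agree
sample by sample, which is exactly what the consistency report measures and
what the synthetic generator makes testable.

# Synthetic cohorts: what they emulate, and what they do not

Every stage is validated by parameter recovery on cohorts from
`make_archetype_profiles()` / `simulate_bulk_cohort()` and
`make_reference_truth()` / `simulate_reference_and_bulk()`.

* Bulk samples are convex mixtures: sample $i$ has expectation
  $\sum_t w_{it}\,a_t$, with weights $w_i \sim \mathrm{Dirichlet}(\alpha)$,
  $\alpha = (1,1,1)$ by default — a flat prior over the simplex, the
  least-informative choice and the one that exercises vertices and interior
  alike. Archetype profiles are sparse gamma draws with per-archetype
  exclusive marker blocks (20 genes by default) so that marker recovery has
  an unambiguous ground truth; profiles are scaled to an expected total of
  10^4 per sample, a realistic pseudo-depth at which Poisson noise has the
  familiar counts behavior.
* Noise is Poisson on expected counts by default; a mean-preserving
  lognormal multiplicative option approximates continuous microarray-like
  intensities. Both are stand-ins: post-summarization microarray noise
  follows neither family exactly, so passing recovery tests demonstrates
  correctness of the algorithms under their own assumptions, not performance
  guarantees on any particular platform.
* The single-cell reference draws each type's mean profile (disjoint
  expressed gene blocks in the benchmark configuration, which makes
  deconvolution exactly solvable and errors attributable), multiplies by
  per-cell gamma noise (shape 20, i.e. ~22% coefficient of variation), and
  places each type as a Gaussian cluster in a synthetic 2D embedding. Only
  the neighborhood structure of the embedding matters to the method, so no
  tSNE/UMAP is computed.
* Not emulated: probe-level microarray physics, batch effects,
  platform-specific normalization, cross-species gene mapping, doublets or
  ambient contamination in the reference.

Validation problem sizes, chosen as the smallest cohorts at which the
asymptotic behavior is already visible: 500 samples x 500 genes for
archetype recovery, 200 x 500 for topic recovery, 300 reference cells
(3 x 100) x 300 genes for deconvolution, and a 30-sample cohort for the
three-way consistency check.

# Preprocessing

* **Probe collapse**: for each gene the probe with the maximal mean across
  all samples is kept, unchanged — never an average. Equal means are broken
  toward the lexicographically smallest probe identifier, a deterministic and
  auditable rule for a case the max-mean convention leaves open.
* **Standardization**: `log2(x + 1)` (the +1 offset keeps zeros finite and
  is immaterial at intensity scale), gene-wise z-scores (n−1 denominator;
  constant genes become 0 with a warning), or none. Whether genes are
  z-scored before PCA or only for display is platform lore rather than a
  defined rule, so both orders are reachable through configuration.
* **Outlier screening**: samples are scored by a robust Mahalanobis-style
  distance in the first 3 PCs (per-component median/MAD), flagged above a
  robust z of 4. The rule replaces by-eye outlier removal with an explicit,
  configurable criterion. As `analysis/02_preprocess.R` demonstrates, on a
  simplex-shaped cohort the most distant samples are the purest ones, so the
  screen reports rather than removes by default.

# Archetype inference

Samples are embedded by centered-SVD PCA (`pca_embed`), with each
component's sign fixed so its largest-magnitude loading is positive. The
archetype fit (`fit_simplex`) minimizes, over vertex positions $V$,

$$\mathrm{vol}(V) \;+\; \lambda \sum_{i}\sum_{t} \max(0, -w_{it}(V)),$$

where $w_i(V)$ are the barycentric coordinates of sample $i$ — a
minimum-volume enclosing simplex with a soft containment relaxation in the
spirit of the Sisal unmixing algorithm: the hinge term charges points
falling outside the simplex linearly in their barycentric violation, so a
few stray points inflate the penalty, not the simplex. Numerical choices:

* $\lambda$ = 10 x the initial simplex volume. The linear (L1) hinge is
  essential: with a squared hinge the penalty gradient vanishes near the
  boundary and the fitted simplex creeps inside the cloud, biasing vertices
  inward by several percent.
* Initialization is a greedy maximum-volume selection of data points
  (inflated 5% about the centroid), refined by BFGS and then by restarted
  Nelder-Mead until no further improvement; the optimum sits on a hinge kink,
  where a single simplex run stalls early. Two additional jittered restarts
  (deterministic given the seed) guard against local minima. Independently
  restarted fits of rotated data agree to about 1e-4 of the cloud scale —
  the documented equivariance tolerance.
* The dimension/order coupling is fixed at $k = d + 1$ (a triangle in the
  default $d = 2$): a full-dimensional simplex is the only polytope this
  fitter addresses, and polytope-order selection is out of scope. Three
  points of a 2D embedding are used by default because the triangular
  continuum is visible in the first two components; $d$ and $k$ remain
  configurable together.
* Vertices are back-projected to gene space through the PCA loadings plus
  center; negative back-projected expression is floored at zero with a
  reported count.

Archetype identity: a gene marks archetype $t$ if its log2 fold change
against **every** other archetype exceeds 2 (pseudocount 1 stabilizes ratios
near zero). Lists are scored against a user marker-set library (GMT) by the
hypergeometric tail probability of the overlap in the matrix's gene
universe; each archetype takes the annotation of its most enriched set, ties
broken by larger overlap then set name, empty lists remaining "unassigned".

# Topic model

Counts $x_{jg}$ are modeled as
$x_{jg} \sim \mathrm{Poisson}\!\big(\sum_t \tilde L_{jt} \tilde F_{gt}\big)$
and fitted by maximum likelihood: 100 multiplicative EM iterations followed
by 100 cyclic Newton coordinate-descent iterations (per-column Newton steps
are exact blocks because samples — respectively genes — are independent
given the other factor). If a CD sweep would decrease the likelihood the
step falls back to an EM update, so the recorded trace is non-decreasing by
construction. The fit is rescaled to the multinomial parameterization
(loadings on the sample simplex, factor columns summing to one), under which
sequencing depth carries no information about topic proportions.

* Initialization: uniform-random positive matrices, deterministic given the
  seed; 3 restarts by default, best final likelihood kept.
* Non-integer input (microarray intensities) is scaled to a common total of
  10^4 per sample and rounded, with a message. The likelihood assumes
  counts; this documented conversion is a stand-in for whatever implicit
  conversion a count-based factorization applies when handed intensities.
* $k = 3$ in all cohort-level drivers because the latent space forms a
  triangle; the fitter itself accepts any $k <\min(G, n)$.

Per-gene topic posteriors follow Bayes' rule,
$p(t \mid g) = F_{gt}\,\pi_t / \sum_s F_{gs}\,\pi_s$, with a uniform prior
$\pi_t = 1/k$ (hence 1/3 for three topics) unless overridden. Genes with
posterior above 0.5 are confidently assigned — any cutoff at or above 0.5
makes the per-topic lists disjoint. Pairwise log2 fold changes between
factor columns use a 1e-10 pseudocount, far below one part in the gene
universe.

# Cellular deconvolution

`cpm_deconvolve` implements the two-step cell-population-mapping procedure:

1. **Deconvolution step.** Linear support vector regression expresses the
   bulk profile as a weighted combination of a random subset of
   `model_size = 50` reference cells. The base number of runs is
   $\lceil \text{min\_selection} \cdot C / \text{model\_size} \rceil$;
   subsets are drawn uniformly without replacement, and extra runs built
   from the most under-sampled cells are appended until every cell has been
   drawn at least `min_selection = 5` times — the expectation-based rule
   turned into a hard guarantee. A cell's raw abundance is the mean of its
   coefficients over the runs in which it was drawn (averaging over all
   runs would shrink every abundance by the constant sampling fraction;
   restricting to drawn runs is the interpretation implemented here).
2. **Extrapolation step.** Abundances are smoothed over the cell-state
   embedding: each cell's value becomes the mean over its
   `neighborhood_size = 10` nearest neighbors (self included, Euclidean
   distance in the provided 2D embedding). Negative values are retained
   through smoothing and clipped at zero only when cell-type proportions are
   formed (per-type sums, normalized to one per sample).

Numerical and design choices that required decisions:

* **Scaling, not centering.** Both matrices are divided gene-wise by the
  reference standard deviation, putting genes on a comparable footing for
  the SVR. Centering is deliberately avoided: the per-gene mean is itself
  (approximately) a convex combination of the reference cells, so after
  centering the regression cannot distinguish weight vectors differing by a
  uniform shift; the SVR intercept and L2 shrinkage then resolve that shift
  arbitrarily, and the clip-then-sum type quantification turns it into a
  large systematic bias toward the dominant type.
* **Convexity anchor.** Because the bulk is modeled as a convex combination
  of cells, a constant row (value 10 in scaled units, for every cell and for
  the bulk) is appended to the regression, softly pinning the coefficient
  sum near one through the regression itself rather than as a
  post-processing constraint. Without it the weight-sum degree of freedom is
  resolved by shrinkage, with the same bias as above.
* **SVR contract**: epsilon-insensitive linear nu-SVR, nu = 0.5, cost = 1,
  fixed across runs; optimizer termination tolerance 0.05 (exposed), at
  which per-coefficient error is far below the subset-sampling noise the
  run-averaging and smoothing remove.
* Cross-species mapping between a reference and the bulk (e.g. mouse
  reference against human arrays) is the caller's responsibility via prior
  gene-identifier harmonization; the package intersects identifiers as
  given.

# Consistency report

Components are aligned as assignment problems solved exactly by permutation
search (k is small): archetypes to the topics whose loadings correlate best
with negative archetype distance, and each cell type grouped to the topic
its proportion tracks best (a user-supplied grouping can override). For each
aligned triple the report carries Pearson correlations across samples;
constant columns give NA rather than an error. The pipeline writes every
stage output plus a manifest of parameters and md5 file hashes, and two runs
from the same configuration produce byte-identical outputs.

# Known limitations

* The simplex fitter addresses only full-dimensional simplices ($k = d+1$)
  and does not select the polytope order statistically.
* Archetype fitting is sensitive to gross outliers by construction (a
  minimum-volume *enclosing* body); the outlier screen exists for that
  reason and requires judgment on continuum-shaped cohorts.
* The topic model's count conversion discards between-sample depth
  differences by design; if depth itself is informative this is a loss.
* Deconvolution accuracy is reported on references with well-separated
  types; closely related types with heavily shared programs will blur into
  each other, and the smoothing step deliberately trades cell-level
  resolution for stability.
* Recovery results quoted anywhere in this package are computed by the test
  suite and `scripts/acceptance.R` on the synthetic benchmark cohorts
  described above; they are statements about those conditions, not about
  any real dataset.
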