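# tricontinuum

Characterization of **continuous transcriptional heterogeneity** in bulk
tumor cohorts, from three independent angles that are checked against each
other:

1. **Archetype inference** — samples are embedded by PCA and enclosed by a
   minimum-volume simplex (Pareto task inference). Its vertices are
   *archetypes*: idealized extreme tumors (e.g. stromal, epithelial,
   blastemal in Wilms' tumor cohorts) between which real samples
   interpolate.
2. **Grade-of-membership (topic) model** — counts are factorized by Poisson
   NMF, `x_{jg} ~ Poisson(Σ_t L_{jt} F_{gt})`, giving per-sample topic
   proportions `L` (rows on the simplex) and per-topic gene distributions
   `F` (columns summing to one), plus Bayes posteriors
   `p(topic|gene) = F_{gt} π_t / Σ_s F_{gs} π_s`.
3. **Cellular deconvolution** — each bulk profile is decomposed over a
   labeled single-cell reference by repeated linear ν-SVR on random 50-cell
   subsets, smoothed over the reference's 2D cell-state embedding, and
   summarized as cell-type proportions.

A synthetic-cohort generator produces ground-truthed convex-mixture data
(Dirichlet weights over archetype profiles; labeled reference cells with a
clustered embedding), so every stage is validated by parameter recovery,
and a consistency report verifies that proximity to an archetype, the
aligned topic loading, and the aligned cell-type proportion rise and fall
together across samples.

The package is aimed at computational biologists analyzing bulk expression
cohorts that form continua rather than clusters, with or without a matched
single-cell reference.

## Worked example

The numbered scripts under `analysis/` run the whole study on a generated
cohort: 30 bulk samples mixed from three single-cell populations
(3 pure samples + 27 Dirichlet draws), analyzed by all three methods.

```sh
Rscript analysis/01_simulate.R     # cohort + reference + truth
Rscript analysis/02_preprocess.R   # probe collapse, outlier screen
Rscript analysis/03_archetypes.R   # PCA + minimum-volume triangle + markers
Rscript analysis/04_topics.R       # k = 3 topics, 100 EM + 100 CD
Rscript analysis/05_deconvolve.R   # CPM against the reference
Rscript analysis/06_consistency.R  # three-way agreement
```

Outputs land under `results/analysis/`. A run prints, among other things:

```
PC1/PC2 explain 55/45% of variance
archetype labels: type1_markers, type2_markers, type3_markers; containment 1;
  marker genes per archetype: 96/93/96
confidently assigned genes per topic: 99/100/100
35 SVR runs; RMSE of type proportions vs generative truth: 0.00546
   archetype   topic archetype_topic_cor topic_type_cor type_group
 archetype_1 topic_3           0.9888583      0.9998860      type2
 archetype_2 topic_2           0.9927843      0.9998342      type3
 archetype_3 topic_1           0.9907050      0.9998286      type1
minimum aligned correlation: 0.989
```

Reading this: the two leading PCs carry all the variance (the cohort is a
true 3-component mixture), the fitted triangle contains every sample and its
vertices are labeled by hypergeometric enrichment against the planted marker
blocks, the topic model confidently assigns ~100 genes per topic (the
planted block size), deconvolution recovers the generating cell-type
proportions to within half a percent, and the three views of every sample
agree with correlations above 0.98 after alignment.

Programmatic use mirrors the scripts:

```r
library(tricontinuum)
emb  <- pca_embed(m, d = 2)                       # m: genes x samples
arch <- fit_simplex(emb, k = 3, seed = 1)
fit  <- fit_topics(m, k = 3, em_iters = 100, cd_iters = 100, seed = 1)
res  <- cpm_deconvolve(m, reference, labels, embedding, seed = 1)
consistency_metrics(arch, emb, fit, res$type_proportions)
```

or a single `run_pipeline(config)` call with a YAML/list configuration.

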