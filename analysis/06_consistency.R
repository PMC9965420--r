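#!/usr/bin/env Rscript
# Cross-method consistency: align archetypes, topics and cell-type groups,
# then correlate, across samples, proximity to each archetype with the
# aligned topic loading, and the topic loading with the aligned cell-type
# proportion. On this single-ground-truth cohort all aligned correlations
# should be strong.

suppressPackageStartupMessages(library(tricontinuum))

out <- "results/analysis"
bulk <- read_expression(file.path(out, "processed.tsv"))

emb <- pca_embed(bulk, d = 2)
arch <- fit_simplex(emb, k = 3, seed = 3)
fit <- fit_topics(bulk, k = 3, em_iters = 100, cd_iters = 100, seed = 4,
                  n_restarts = 3)
props <- t(read_expression(file.path(out, "type_proportions.tsv"),
                           allow_negative = TRUE))

report <- consistency_metrics(arch, emb, fit, type_proportions = props)
print(report)

utils::write.table(report$per_sample,
                   file.path(out, "consistency_per_sample.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(report$correlations,
                   file.path(out, "consistency_correlations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("minimum aligned correlation: ",
        round(min(c(report$correlations$archetype_topic_cor,
                    report$correlations$topic_type_cor)), 3))
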