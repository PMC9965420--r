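#!/usr/bin/env Rscript
# Deconvolution view: estimate the abundance of every reference cell in each
# bulk sample by repeated linear SVR over random 50-cell subsets (every cell
# drawn at least 5 times), smooth abundances over the 10 nearest neighbors in
# the cell-state embedding, and quantify cell-type proportions.

suppressPackageStartupMessages(library(tricontinuum))

out <- "results/analysis"
bulk <- read_expression(file.path(out, "bulk.tsv"))
ref <- read_expression(file.path(out, "reference.tsv"))
labels <- utils::read.table(file.path(out, "labels.tsv"), header = TRUE,
                            sep = "\t")$cell_type
emb <- as.matrix(utils::read.table(file.path(out, "embedding.tsv"),
                                   header = TRUE, sep = "\t", row.names = 1))

res <- cpm_deconvolve(bulk, ref, labels, emb, model_size = 50,
                      min_selection = 5, neighborhood_size = 10, seed = 5)
print(res)

write_expression(t(res$cell_abundance), file.path(out, "cell_abundance.tsv"),
                 id_col = "cell_id")
write_expression(t(res$type_proportions),
                 file.path(out, "type_proportions.tsv"), id_col = "cell_type")

truth <- jsonlite::read_json(file.path(out, "truth.json"),
                             simplifyVector = TRUE)$bulk_composition
rmse <- sqrt(mean((res$type_proportions - truth)^2))
message(res$runs, " SVR runs; RMSE of type proportions vs generative truth: ",
        signif(rmse, 3))
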