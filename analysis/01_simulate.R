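#!/usr/bin/env Rscript
# Build the ground-truthed study cohort every later stage analyzes: a labeled
# single-cell reference with three transcriptionally distinct populations and
# 30 bulk samples mixed from those populations (3 pure, 27 Dirichlet draws).
# Because one generative truth drives all samples, the archetype, topic and
# deconvolution views of the cohort can later be checked against each other
# and against the recorded composition.

suppressPackageStartupMessages(library(tricontinuum))

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(1)

comp <- rbind(diag(3), rdirichlet(27, c(1, 1, 1)))
truth <- make_reference_truth(n_types = 3, cells_per_type = 100,
                              n_genes = 300, disjoint_support = TRUE,
                              bulk_composition = comp, noise_model = "none",
                              seed = 11)
sim <- simulate_reference_and_bulk(truth)

write_expression(sim$bulk, file.path(out, "bulk.tsv"))
write_expression(sim$reference, file.path(out, "reference.tsv"),
                 id_col = "gene_id")
utils::write.table(data.frame(cell_id = names(sim$labels),
                              cell_type = sim$labels),
                   file.path(out, "labels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(cell_id = rownames(sim$embedding),
                              sim$embedding),
                   file.path(out, "embedding.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(bulk_composition = truth$bulk_composition,
                          seed = truth$seed),
                     file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

# marker blocks: genes expressed by exactly one type, usable as a GMT library
expressed <- vapply(paste0("type", 1:3), function(t)
  rowSums(sim$reference[, sim$labels == t]) > 0, logical(nrow(sim$reference)))
blocks <- lapply(paste0("type", 1:3), function(t)
  rownames(sim$reference)[expressed[, t] & rowSums(expressed) == 1])
names(blocks) <- paste0(c("type1", "type2", "type3"), "_markers")
write_gmt(blocks, file.path(out, "marker_blocks.gmt"))

message("cohort: ", ncol(sim$bulk), " bulk samples, ",
        ncol(sim$reference), " reference cells, ",
        nrow(sim$bulk), " genes; marker blocks of sizes ",
        paste(lengths(blocks), collapse = "/"))
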