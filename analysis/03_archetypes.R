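#!/usr/bin/env Rscript
# Archetype view: embed the cohort by PCA, fit the minimum-volume enclosing
# triangle, back-project its vertices to gene space, extract per-archetype
# marker genes (log2 fold change > 2 against both other archetypes) and label
# each archetype against the marker-block library by hypergeometric
# enrichment.

suppressPackageStartupMessages(library(tricontinuum))

out <- "results/analysis"
bulk <- read_expression(file.path(out, "processed.tsv"))
lib <- read_gmt(file.path(out, "marker_blocks.gmt"))

emb <- pca_embed(bulk, d = 2)
message("PC1/PC2 explain ",
        paste(round(100 * emb$explained_variance_ratio, 1), collapse = "/"),
        "% of variance")

arch <- fit_simplex(emb, k = 3, seed = 3)
arch <- label_archetypes(arch, lib, rownames(bulk))
print(arch)

utils::write.table(data.frame(archetype = rownames(arch$vertices),
                              arch$vertices, label = arch$labels),
                   file.path(out, "archetypes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
lists <- archetype_markers(arch, fc_threshold = 2)
write_gmt(lists, file.path(out, "archetype_markers.gmt"))
utils::write.table(attr(arch, "enrichment"),
                   file.path(out, "archetype_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("archetype labels: ", paste(arch$labels, collapse = ", "),
        "; containment ",
        round(arch$fit_diagnostics$containment_fraction, 3),
        "; marker genes per archetype: ",
        paste(lengths(lists), collapse = "/"))
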