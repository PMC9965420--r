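#' Collapse a probe-level table to one row per gene by maximal mean
#'
#' For each gene, keeps the single probe whose mean across all samples is
#' maximal; no averaging is performed, so every output row equals one input
#' probe row exactly. Equal means are broken in favor of the
#' lexicographically smallest probe identifier, which makes the choice
#' deterministic and auditable.
#'
#' @param probe_table probes x samples matrix (probe ids as rownames).
#' @param probe_map data.frame with columns probe_id, gene_id
#'   (see [read_probe_map()]).
#' @return genes x samples matrix; attribute "dropped_genes" counts mapped
#'   genes that had no probe present in the table, attribute "chosen_probes"
#'   records the winning probe per gene.
#' @export
collapse_probes <- function(probe_table, probe_map) {
  validate_expression(probe_table, allow_negative = TRUE)
  map <- probe_map[probe_map$probe_id %in% rownames(probe_table), , drop = FALSE]
  if (nrow(map) == 0) stop("no probe in the map is present in the table")
  dropped <- setdiff(unique(probe_map$gene_id), unique(map$gene_id))
  if (length(dropped))
    message(length(dropped), " mapped gene(s) had no probe in the table and were dropped")
  probe_means <- rowMeans(probe_table)[map$probe_id]
  # sort by gene, then mean descending, then probe id ascending: the first
  # row per gene is the max-mean winner with the lexicographic tie-break
  ord <- order(map$gene_id, -probe_means, map$probe_id)
  map <- map[ord, , drop = FALSE]
  keep <- !duplicated(map$gene_id)
  chosen <- map$probe_id[keep]
  out <- probe_table[chosen, , drop = FALSE]
  rownames(out) <- map$gene_id[keep]
  attr(out, "dropped_genes") <- length(dropped)
  attr(out, "chosen_probes") <- stats::setNames(chosen, map$gene_id[keep])
  out
}

#' Standardize an expression matrix
#'
#' `log2` applies log2(x + 1) entrywise (requires non-negative input);
#' `zscore_rows` centers and scales each gene to mean 0, sd 1 (n - 1
#' denominator), setting constant rows to 0 with a warning; `none` returns
#' the input unchanged.
#'
#' @param m genes x samples matrix.
#' @param mode one of "log2", "zscore_rows", "none".
#' @return transformed matrix of the same shape.
#' @export
standardize <- function(m, mode = c("log2", "zscore_rows", "none")) {
  mode <- match.arg(mode)
  switch(mode,
    none = m,
    log2 = {
      if (any(m < 0)) stop("log2 mode requires non-negative input")
      log2(m + 1)
    },
    zscore_rows = {
      mu <- rowMeans(m)
      sdv <- apply(m, 1, stats::sd)
      const <- sdv == 0
      if (any(const)) {
        warning(sum(const), " constant row(s) set to 0 under zscore")
        sdv[const] <- 1
      }
      (m - mu) / sdv
    })
}

#' Flag outlier samples by robust distance in PCA space
#'
#' Samples are scored by their distance from the cohort's center in the first
#' `n_pcs` principal components, with each component scaled by its median
#' absolute deviation (a Mahalanobis-style distance robust to the outliers it
#' is hunting). A sample is flagged when the robust z-score of its distance
#' exceeds `z_cut`. The default of three components mirrors common practice
#' of inspecting the leading latent space for aberrant arrays.
#'
#' @param embedding a [pca_embed()] result (or any list with a `coords`
#'   matrix, samples x d).
#' @param n_pcs number of leading components used (default 3).
#' @param z_cut robust z threshold (default 4).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outliers <- function(embedding, n_pcs = 3, z_cut = 4) {
  coords <- embedding$coords
  if (nrow(coords) < 4) stop("need at least 4 samples to estimate spread")
  n_pcs <- min(n_pcs, ncol(coords))
  x <- coords[, seq_len(n_pcs), drop = FALSE]
  med <- apply(x, 2, stats::median)
  scale <- apply(x, 2, stats::mad)
  scale[scale == 0] <- 1
  d <- sqrt(rowSums(sweep(sweep(x, 2, med), 2, scale, "/")^2))
  spread <- stats::mad(d)
  if (spread == 0) return(character(0))
  z <- (d - stats::median(d)) / spread
  rownames(coords)[z > z_cut]
}
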