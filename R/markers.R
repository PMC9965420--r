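#' Genes over-expressed in one archetype versus all others
#'
#' A gene is assigned to archetype t when its log2 fold change against every
#' other archetype exceeds `fc_threshold` (default 2, i.e. at least four-fold
#' higher), with a pseudocount to stabilize ratios near zero. With k = 3 this
#' is the "larger than two with respect to the other two archetypes" rule.
#'
#' @param archetypes an [fit_simplex()] result, or a k x G profile matrix.
#' @param fc_threshold log2 fold-change cutoff (default 2).
#' @param pseudocount added to numerator and denominator (default 1).
#' @return named list (one element per archetype) of gene identifier vectors.
#' @export
archetype_markers <- function(archetypes, fc_threshold = 2, pseudocount = 1) {
  prof <- if (inherits(archetypes, "archetype_set")) archetypes$gene_profiles
          else as.matrix(archetypes)
  k <- nrow(prof)
  if (k < 2) stop("marker comparison needs at least 2 archetypes")
  lp <- log2(prof + pseudocount)
  out <- vector("list", k)
  for (t in seq_len(k)) {
    others <- lp[-t, , drop = FALSE]
    pass <- lp[t, ] - apply(others, 2, max) > fc_threshold
    out[[t]] <- colnames(prof)[pass]
  }
  names(out) <- rownames(prof)
  out
}

#' Score archetype gene lists against a marker-set library
#'
#' Each archetype's gene list is tested for over-representation in every
#' library set with a hypergeometric tail probability (the chance of an
#' overlap at least as large, drawing the list at random from the gene
#' universe). Each archetype is labeled with the annotation of its most
#' enriched set; ties are broken by larger overlap, then by set name. An
#' empty gene list gets the label "unassigned".
#'
#' @param marker_lists named list of per-archetype gene vectors
#'   (from [archetype_markers()] or [topic_gene_lists()]).
#' @param library named list of marker gene sets (see [read_gmt()]).
#' @param universe character vector of all genes in the analyzed matrix.
#' @return list: `labels` (named character, per archetype) and `enrichment`
#'   (data.frame: archetype, set, overlap, list_size, set_size, p_value).
#' @export
score_markers <- function(marker_lists, library, universe) {
  universe <- unique(universe)
  N <- length(universe)
  rows <- list()
  labels <- character(length(marker_lists))
  names(labels) <- names(marker_lists)
  for (a in names(marker_lists)) {
    glist <- intersect(marker_lists[[a]], universe)
    res <- data.frame(archetype = a, set = names(library),
                      overlap = NA_integer_, list_size = length(glist),
                      set_size = NA_integer_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    for (i in seq_along(library)) {
      set <- intersect(library[[i]], universe)
      ov <- length(intersect(glist, set))
      res$overlap[i] <- ov
      res$set_size[i] <- length(set)
      # P(X >= ov) drawing list_size genes from a universe with set_size hits
      res$p_value[i] <- stats::phyper(ov - 1, length(set), N - length(set),
                                      length(glist), lower.tail = FALSE)
    }
    rows[[a]] <- res
    if (length(glist) == 0 || all(res$overlap == 0)) {
      labels[a] <- "unassigned"
    } else {
      ord <- order(res$p_value, -res$overlap, res$set)
      labels[a] <- res$set[ord[1]]
    }
  }
  list(labels = labels, enrichment = do.call(rbind, rows))
}

#' Attach marker-derived labels to an archetype set
#'
#' Convenience wrapper: derives per-archetype gene lists, scores them against
#' the library, and writes the winning labels into the archetype set. Rows of
#' `vertices` and `gene_profiles` are re-ordered alphabetically by label
#' (unlabeled archetypes keep their vertex-angle order at the end).
#'
#' @param archetypes an [fit_simplex()] result.
#' @param library marker-set library (named list).
#' @param universe all genes in the analyzed matrix.
#' @param fc_threshold passed to [archetype_markers()].
#' @return the archetype set with `labels` filled and rows re-ordered;
#'   the enrichment table is attached as attribute "enrichment".
#' @export
label_archetypes <- function(archetypes, library, universe, fc_threshold = 2) {
  lists <- archetype_markers(archetypes, fc_threshold = fc_threshold)
  sc <- score_markers(lists, library, universe)
  labels <- unname(sc$labels)
  assigned <- labels != "unassigned"
  ord <- c(which(assigned)[order(labels[assigned])], which(!assigned))
  archetypes$vertices <- archetypes$vertices[ord, , drop = FALSE]
  archetypes$gene_profiles <- archetypes$gene_profiles[ord, , drop = FALSE]
  archetypes$labels <- labels[ord]
  rownames(archetypes$vertices) <- rownames(archetypes$gene_profiles) <-
    make.unique(archetypes$labels)
  attr(archetypes, "enrichment") <- sc$enrichment
  archetypes
}
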