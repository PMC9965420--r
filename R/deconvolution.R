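#' Cell-population deconvolution by repeated linear SVR
#'
#' Estimates the abundance of every reference single cell in each bulk sample
#' in two steps. Deconvolution: linear nu-support-vector regression expresses
#' the (per-gene standardized) bulk profile as a weighted combination of a
#' random subset of `model_size` reference cells; the regression is repeated
#' over enough subsets that every cell is drawn at least `min_selection`
#' times, and a cell's raw abundance is the mean of its coefficients over the
#' runs in which it was drawn. Extrapolation: the raw abundances are smoothed
#' over the cell-state embedding by averaging each cell with its
#' `neighborhood_size` nearest neighbors (self included), which propagates
#' signal along the continuum of cell states. Cell-type proportions are the
#' per-type sums of the smoothed abundances after clipping negatives at zero,
#' normalized to one.
#'
#' The base number of runs is `ceiling(min_selection * C / model_size)` with
#' subsets drawn uniformly without replacement; if any cell is still drawn
#' fewer than `min_selection` times, extra runs built from the most
#' under-sampled cells are appended until the guarantee holds.
#'
#' Both matrices are scaled per gene by the reference standard deviation
#' (computed over cells), which puts all genes on a comparable footing for
#' the SVR without centering them: centering is deliberately avoided because
#' it makes the regression blind to a uniform shift of all cell weights, an
#' ambiguity the intercept then resolves arbitrarily and the clip-then-sum
#' type quantification inherits as bias. Genes constant in the reference are
#' dropped. Because the bulk profile is modeled as a convex combination of
#' cell profiles, a constant anchor row (value `anchor` for every cell and
#' for the bulk) is appended, which softly pins the weight sum near one
#' through the regression itself. The SVR is the epsilon-insensitive linear
#' machine with nu = 0.5 and cost = 1, fixed across runs.
#'
#' @param bulk genes x samples matrix.
#' @param reference genes x cells matrix.
#' @param labels per-cell type labels (named by cell or in column order).
#' @param embedding cells x 2 cell-state coordinates.
#' @param model_size cells per regression subset (default 50).
#' @param min_selection minimum number of draws guaranteed per cell
#'   (default 5).
#' @param neighborhood_size neighbors used in smoothing, self included
#'   (default 10).
#' @param seed integer seed controlling the subset draws.
#' @param anchor value of the appended sum-to-one anchor row, in units of the
#'   scaled data (default 10; 0 disables the anchor).
#' @param svr_tolerance termination tolerance of the SVR optimizer (default
#'   0.05; coefficient error at this tolerance is far below the sampling
#'   noise that the run-averaging and neighborhood smoothing remove).
#' @return object of class "cpm_result": `cell_abundance` (samples x cells,
#'   smoothed), `raw_abundance`, `type_proportions` (samples x types, rows
#'   sum to 1), `runs`, `sampling_counts`, `params`.
#' @export
cpm_deconvolve <- function(bulk, reference, labels, embedding,
                           model_size = 50, min_selection = 5,
                           neighborhood_size = 10, seed = 1L,
                           anchor = 10, svr_tolerance = 0.05) {
  validate_expression(bulk); validate_expression(reference)
  C <- ncol(reference)
  if (C < model_size) stop("reference has fewer cells (", C,
                           ") than model_size (", model_size, ")")
  labels <- as.character(labels)
  if (length(labels) != C) stop("need one label per reference cell")
  if (nrow(embedding) != C) stop("embedding must have one row per cell")

  genes <- intersect(rownames(bulk), rownames(reference))
  if (length(genes) < 2) stop("bulk and reference share too few genes")
  ref <- reference[genes, , drop = FALSE]
  blk <- bulk[genes, , drop = FALSE]
  sdv <- apply(ref, 1, stats::sd)
  keep <- sdv > 0
  Zr <- ref[keep, , drop = FALSE] / sdv[keep]
  Zb <- blk[keep, , drop = FALSE] / sdv[keep]
  n <- ncol(Zb)

  with_seed(seed, {
    plan <- plan_draws(C, model_size, min_selection)
    draws <- plan$draws
    counts <- plan$counts
    N <- length(draws)

    coef_sum <- matrix(0, n, C)
    coef_n <- matrix(0L, n, C)
    for (run in draws) {
      Xr <- Zr[, run, drop = FALSE]
      if (anchor > 0) Xr <- rbind(Xr, anchor)
      for (j in seq_len(n)) {
        y <- Zb[, j]
        if (anchor > 0) y <- c(y, anchor)
        if (stats::sd(y) == 0) {
          warning("bulk sample ", colnames(Zb)[j],
                  " has zero variance; abundances set to 0")
          next
        }
        fit <- e1071::svm(x = Xr, y = y, type = "nu-regression",
                          kernel = "linear", nu = 0.5, cost = 1,
                          scale = FALSE, tolerance = svr_tolerance)
        w <- as.numeric(t(fit$coefs) %*% fit$SV)
        coef_sum[j, run] <- coef_sum[j, run] + w
        coef_n[j, run] <- coef_n[j, run] + 1L
      }
    }
    raw <- coef_sum / pmax(coef_n, 1L)
    dimnames(raw) <- list(colnames(Zb), colnames(Zr))

    nn <- embedding_neighbors(embedding, neighborhood_size)
    smoothed <- t(apply(raw, 1, function(a)
      vapply(seq_len(C), function(c) mean(a[nn[[c]]]), numeric(1))))
    dimnames(smoothed) <- dimnames(raw)

    res <- structure(list(cell_abundance = smoothed, raw_abundance = raw,
                          type_proportions = NULL, runs = N,
                          sampling_counts = counts, labels = labels,
                          params = list(model_size = model_size,
                                        min_selection = min_selection,
                                        neighborhood_size = neighborhood_size,
                                        nu = 0.5, cost = 1, anchor = anchor,
                                        svr_tolerance = svr_tolerance,
                                        seed = seed)),
                     class = "cpm_result")
    res$type_proportions <- quantify_types(res, labels)
    res
  })
}

#' Plan the random cell subsets for the repeated regressions
#'
#' Draws `ceiling(min_selection * C / model_size)` subsets of `model_size`
#' cells uniformly without replacement, then appends subsets built from the
#' most under-sampled cells until every cell appears at least `min_selection`
#' times — the expectation-based run count turned into a hard guarantee.
#' Uses the caller's RNG stream.
#'
#' @param C number of reference cells.
#' @param model_size subset size.
#' @param min_selection minimum draws guaranteed per cell.
#' @return list: `draws` (list of index vectors) and `counts` (per-cell draw
#'   counts).
#' @export
plan_draws <- function(C, model_size, min_selection) {
  N0 <- ceiling(min_selection * C / model_size)
  draws <- lapply(seq_len(N0), function(i) sample.int(C, model_size))
  counts <- tabulate(unlist(draws), nbins = C)
  while (any(counts < min_selection)) {         # top-up: target the deficit
    deficit <- order(counts, stats::runif(C))[seq_len(model_size)]
    draws <- c(draws, list(deficit))
    counts <- counts + tabulate(deficit, nbins = C)
  }
  list(draws = draws, counts = counts)
}

# index lists of the k nearest cells (self included) in the 2D embedding
embedding_neighbors <- function(embedding, k) {
  D <- as.matrix(stats::dist(embedding))
  lapply(seq_len(nrow(D)), function(i) order(D[i, ])[seq_len(min(k, ncol(D)))])
}

#' Cell-type proportions from smoothed cell abundances
#'
#' Negative smoothed abundances are clipped to zero, summed within each cell
#' type and normalized to one per sample. A sample whose abundances are all
#' zero after clipping gets uniform proportions with a warning.
#'
#' @param result a [cpm_deconvolve()] result (or a samples x cells abundance
#'   matrix).
#' @param labels per-cell type labels.
#' @return samples x types matrix, rows summing to 1.
#' @export
quantify_types <- function(result, labels) {
  A <- if (inherits(result, "cpm_result")) result$cell_abundance
       else as.matrix(result)
  labels <- as.character(labels)
  if (length(labels) != ncol(A)) stop("need one label per cell")
  A <- pmax(A, 0)
  types <- sort(unique(labels))
  P <- vapply(types, function(t) rowSums(A[, labels == t, drop = FALSE]),
              numeric(nrow(A)))
  P <- matrix(P, nrow = nrow(A), dimnames = list(rownames(A), types))
  tot <- rowSums(P)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with all-zero abundance set to uniform proportions")
    P[zero, ] <- 1 / length(types)
    tot[zero] <- 1
  }
  P / tot
}

#' @export
print.cpm_result <- function(x, ...) {
  cat("CPM deconvolution:", nrow(x$cell_abundance), "bulk samples,",
      ncol(x$cell_abundance), "reference cells,", x$runs, "SVR runs\n")
  cat("  min per-cell sampling count:", min(x$sampling_counts), "\n")
  cat("  cell types:", paste(colnames(x$type_proportions), collapse = ", "),
      "\n")
  invisible(x)
}
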