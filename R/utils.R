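#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a gene-by-sample expression matrix
#'
#' The exchange object for every stage is a plain numeric matrix with unique
#' gene identifiers as rownames and unique sample identifiers as colnames,
#' finite and non-negative throughout.
#'
#' @param m numeric matrix, genes in rows and samples in columns.
#' @param allow_negative allow negative entries (used for standardized data).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression <- function(m, allow_negative = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(m))) stop("duplicated sample identifiers")
  if (anyNA(m) || any(!is.finite(m))) stop("expression contains NA/Inf")
  if (!allow_negative && any(m < 0)) stop("expression contains negative values")
  invisible(m)
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha positive concentration parameters, length k.
#' @return n x k matrix whose rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("Dirichlet concentration parameters must be positive")
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  # guard against all-zero rows at tiny alpha
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k
  g / rowSums(g)
}

#' Optimal component matching by exhaustive permutation
#'
#' Aligns k fitted components to k reference components by minimizing the
#' total pairwise cost over all permutations (k is small in this pipeline, so
#' exhaustive search is exact and cheap).
#'
#' @param cost k x k matrix; cost[i, j] of assigning fitted i to reference j.
#' @return integer vector p with fitted component p[j] matched to reference j.
#' @export
match_components <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  perms <- all_permutations(k)
  totals <- apply(perms, 1, function(p) sum(cost[cbind(p, seq_len(k))]))
  perms[which.min(totals), ]
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# local seed scope: evaluates expr under a seed without clobbering the
# caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
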