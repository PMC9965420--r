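#' Volume of a k-vertex simplex in (k-1) dimensions
#'
#' @param vertices k x d matrix with k = d + 1.
#' @return simplex volume (area for a triangle).
#' @export
simplex_volume <- function(vertices) {
  d <- ncol(vertices)
  edges <- sweep(vertices[-1, , drop = FALSE], 2, vertices[1, ], "-")
  abs(det(edges)) / factorial(d)
}

#' Barycentric coordinates of points with respect to a simplex
#'
#' @param points n x d matrix.
#' @param vertices k x d simplex vertices, k = d + 1.
#' @return n x k matrix of barycentric weights (rows sum to 1; negative
#'   entries mean the point lies outside the simplex).
#' @export
barycentric_coords <- function(points, vertices) {
  M <- rbind(t(vertices), 1)                       # (d+1) x k
  W <- solve(M, rbind(t(points), 1))               # k x n
  t(W)
}

#' Fit the minimum-volume enclosing simplex (archetype inference)
#'
#' Finds the k vertices (k = d + 1, a triangle in two dimensions) of the
#' smallest simplex that encloses the embedded samples, under a soft
#' containment relaxation in the spirit of the Sisal unmixing algorithm: the
#' objective is the simplex volume plus a hinge penalty on the barycentric
#' violation of points falling outside, so a few stray points inflate the
#' penalty rather than the simplex. Vertices are the inferred archetypes —
#' idealized extreme profiles between which the samples interpolate.
#'
#' Initialization is a greedy maximum-volume selection of data points,
#' slightly inflated about the centroid; `n_restarts - 1` jittered restarts
#' (deterministic given `seed`) guard against local minima and the best
#' objective is kept. Vertices are ordered by angle about the centroid so the
#' output is stable.
#'
#' @param embedding a [pca_embed()] result (d-dimensional).
#' @param k number of archetypes; must equal d + 1.
#' @param penalty_weight weight of the containment penalty, in units of the
#'   initial simplex volume (default 10).
#' @param tolerance barycentric slack below which a point still counts as
#'   contained in the diagnostics (default 1e-9).
#' @param seed integer seed for the restart jitter.
#' @param n_restarts number of optimization starts (default 3).
#' @return object of class "archetype_set": `vertices` (k x d), `gene_profiles`
#'   (k x G back-projections), `labels` (filled by [score_markers()]),
#'   `fit_diagnostics` (containment fraction, volume, objective).
#' @export
fit_simplex <- function(embedding, k = NULL, penalty_weight = 10,
                        tolerance = 1e-9, seed = 1L, n_restarts = 3) {
  X <- embedding$coords
  d <- ncol(X)
  if (is.null(k)) k <- d + 1L
  if (k != d + 1) stop("k must equal d + 1 (a full-dimensional simplex); got k = ",
                       k, " with d = ", d)
  if (nrow(X) < k) stop("need at least k samples")
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv[d] < 1e-9 * sv[1])
    stop("embedding is rank-deficient (rank < ", d,
         "); lower d to match the data's intrinsic dimension")

  V0 <- greedy_vertex_init(X, k)
  ctr <- colMeans(X)
  V0 <- sweep(sweep(V0, 2, ctr, "-") * 1.05, 2, ctr, "+")
  vol0 <- simplex_volume(V0)
  if (vol0 <= 0) stop("degenerate initial simplex")
  lambda <- penalty_weight * vol0

  objective <- function(par) {
    V <- matrix(par, k, d)
    M <- rbind(t(V), 1)
    dt <- det(M)
    if (abs(dt) < 1e-12 * vol0) return(1e6 * vol0)
    W <- solve(M, rbind(t(X), 1))
    vol <- abs(dt) / factorial(d)
    vol + lambda * sum(pmax(-W, 0))
  }

  refine <- function(V) {
    fit <- stats::optim(as.vector(V), objective, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    # restarted Nelder-Mead: the optimum sits on a hinge kink, so a single
    # simplex run stalls early; restarting until no further improvement
    # recovers high precision
    repeat {
      nxt <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-15))
      if (nxt$value >= fit$value - 1e-12 * (abs(fit$value) + vol0)) {
        if (nxt$value < fit$value) fit <- nxt
        break
      }
      fit <- nxt
    }
    fit
  }

  best <- refine(V0)
  cand <- refine(greedy_vertex_init(X, k))      # uninflated hull start
  if (cand$value < best$value) best <- cand
  if (n_restarts > 1) {
    scale0 <- sqrt(mean(scale(X, center = TRUE, scale = FALSE)^2))
    jitters <- with_seed(seed, lapply(seq_len(n_restarts - 1), function(i)
      matrix(stats::rnorm(k * d, sd = 0.05 * scale0), k, d)))
    for (J in jitters) {
      cand <- refine(V0 + J)
      if (cand$value < best$value) best <- cand
    }
  }
  V <- matrix(best$par, k, d)
  # stable output order: by angle about the centroid (2D), else by first axis
  ctrV <- colMeans(V)
  ord <- if (d == 2) order(atan2(V[, 2] - ctrV[2], V[, 1] - ctrV[1])) else
    order(V[, 1])
  V <- V[ord, , drop = FALSE]
  rownames(V) <- sprintf("archetype_%d", seq_len(k))
  colnames(V) <- colnames(X)

  W <- barycentric_coords(X, V)
  containment <- mean(apply(W, 1, function(w) all(w >= -tolerance - 1e-12)))
  profiles <- NULL
  if (!is.null(embedding$loadings)) {           # bare coords: latent-only fit
    profiles <- suppressMessages(backproject(V, embedding))
    rownames(profiles) <- rownames(V)
  }
  structure(list(vertices = V, gene_profiles = profiles,
                 labels = rownames(V),
                 fit_diagnostics = list(containment_fraction = containment,
                                        volume = simplex_volume(V),
                                        objective = best$value)),
            class = "archetype_set")
}

# greedy max-volume selection of k data points: start from the point farthest
# from the centroid, then add the point maximizing the simplex volume spanned
greedy_vertex_init <- function(X, k) {
  ctr <- colMeans(X)
  idx <- which.max(rowSums(sweep(X, 2, ctr, "-")^2))
  for (j in 2:k) {
    span <- function(i) {
      V <- X[c(idx, i), , drop = FALSE]
      E <- sweep(V[-1, , drop = FALSE], 2, V[1, ], "-")
      sqrt(abs(det(tcrossprod(E))))
    }
    vols <- vapply(seq_len(nrow(X)), span, numeric(1))
    vols[idx] <- -Inf
    idx <- c(idx, which.max(vols))
  }
  X[idx, , drop = FALSE]
}

#' @export
print.archetype_set <- function(x, ...) {
  cat("Archetype set:", nrow(x$vertices), "vertices in",
      ncol(x$vertices), "latent dimensions\n")
  cat("  containment fraction:",
      format(x$fit_diagnostics$containment_fraction, digits = 4), "\n")
  cat("  simplex volume:", format(x$fit_diagnostics$volume, digits = 4), "\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
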