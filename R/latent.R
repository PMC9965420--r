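#' Embed samples by centered-SVD PCA
#'
#' Samples are embedded by principal component analysis of the gene-by-sample
#' matrix (centered features, SVD). The sign of each component is fixed so
#' that its largest-magnitude gene loading is positive, which makes the
#' embedding reproducible across platforms.
#'
#' @param m genes x samples matrix.
#' @param d number of components to keep; must satisfy d <= min(G, n - 1).
#' @return object of class "latent_embedding": `coords` (n x d scores),
#'   `loadings` (G x d), `center` (gene means), `explained_variance_ratio`
#'   (share of total variance per kept component).
#' @export
pca_embed <- function(m, d = 2) {
  validate_expression(m, allow_negative = TRUE)
  n <- ncol(m); G <- nrow(m)
  if (d > min(G, n - 1))
    stop("d must be <= min(G, n - 1) = ", min(G, n - 1))
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  keep <- seq_len(d)
  coords <- pr$x[, keep, drop = FALSE]
  loadings <- pr$rotation[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  tot <- sum(pr$sdev^2)
  evr <- if (tot > 0) pr$sdev^2 / tot else rep(0, length(pr$sdev))
  structure(list(coords = coords, loadings = loadings, center = pr$center,
                 explained_variance_ratio = evr[keep]),
            class = "latent_embedding")
}

#' Back-project latent points to gene space
#'
#' A latent point v maps to the gene profile `center + v %*% t(loadings)`.
#' Negative back-projected values (possible because PCA is unconstrained) are
#' floored at zero with a reported count, so archetype profiles remain valid
#' expression vectors.
#'
#' @param points matrix of latent coordinates (rows are points) or a single
#'   vector.
#' @param embedding a [pca_embed()] result.
#' @return points x genes matrix of non-negative profiles; attribute
#'   "n_floored" counts clipped entries.
#' @export
backproject <- function(points, embedding) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  prof <- sweep(points %*% t(embedding$loadings), 2, embedding$center, "+")
  n_neg <- sum(prof < 0)
  if (n_neg > 0) {
    message(n_neg, " negative back-projected value(s) floored at 0")
    prof[prof < 0] <- 0
  }
  colnames(prof) <- names(embedding$center)
  attr(prof, "n_floored") <- n_neg
  prof
}
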