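#' Fit a grade-of-membership (topic) model by Poisson NMF
#'
#' Models each sample's expression vector as a mixture of k latent topics:
#' counts x_gj ~ Poisson( sum_t Lt[j] * Ft[g] ), maximized by multiplicative
#' expectation-maximization updates followed by cyclic Newton coordinate
#' descent (the classic two-phase schedule: EM moves fast early, coordinate
#' descent sharpens the optimum). The fitted factorization is rescaled to the
#' multinomial topic-model parameterization: loadings L give per-sample topic
#' proportions (rows on the simplex) and factors F give per-topic gene
#' distributions (columns sum to one) — the depth of a sample carries no
#' information about its topic proportions under this equivalence.
#'
#' Non-integer input (e.g. microarray intensities) is converted to pseudo
#' counts by scaling every sample to a common target total and rounding; the
#' conversion is reported. All-zero gene rows are dropped with a warning.
#'
#' @param m genes x samples matrix of non-negative values.
#' @param k number of topics (>= 2; k = 1 is allowed for the rank-1 baseline).
#' @param em_iters EM iterations (default 100).
#' @param cd_iters coordinate-descent iterations (default 100). If a CD sweep
#'   would decrease the likelihood it is replaced by an EM step, so the
#'   likelihood trace is non-decreasing by construction.
#' @param seed integer seed for initialization.
#' @param n_restarts independent initializations; the best final likelihood
#'   is kept (default 3).
#' @param target_total per-sample total used when converting non-integer
#'   input to counts (default 1e4).
#' @return object of class "topic_fit": `L` (n x k, rows sum to 1), `F`
#'   (G x k, columns sum to 1), `k`, `loglik_trace` (per-iteration Poisson
#'   log-likelihood of the kept restart), `seed`, `sample_totals`.
#' @export
fit_topics <- function(m, k, em_iters = 100, cd_iters = 100, seed = 1L,
                       n_restarts = 3, target_total = 1e4) {
  validate_expression(m)
  if (k >= min(nrow(m), ncol(m))) stop("k must be < min(G, n)")
  if (k < 1) stop("k must be >= 1")
  X <- t(m)                                       # n x G, samples in rows
  if (any(X != round(X))) {
    message("non-integer input: samples rescaled to total ", target_total,
            " and rounded to counts")
    X <- round(X / rowSums(X) * target_total)
  }
  zero_genes <- colSums(X) == 0
  if (any(zero_genes)) {
    warning(sum(zero_genes), " all-zero gene row(s) dropped before fitting")
    X <- X[, !zero_genes, drop = FALSE]
  }
  n <- nrow(X); G <- ncol(X)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + (r - 1L) * 1000L,
                     poisson_nmf(X, k, em_iters, cd_iters))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # rescale to the multinomial parameterization
  u <- colSums(best$F)
  Fm <- sweep(best$F, 2, u, "/")
  Lu <- sweep(best$L, 2, u, "*")
  Lm <- Lu / rowSums(Lu)
  dimnames(Lm) <- list(rownames(X), sprintf("topic_%d", seq_len(k)))
  dimnames(Fm) <- list(colnames(X), sprintf("topic_%d", seq_len(k)))
  structure(list(L = Lm, F = Fm, k = k, loglik_trace = best$trace,
                 seed = as.integer(seed), sample_totals = rowSums(X)),
            class = "topic_fit")
}

# core Poisson NMF: EM (multiplicative) then Newton CD, monotone by guard
poisson_nmf <- function(X, k, em_iters, cd_iters) {
  n <- nrow(X); G <- ncol(X)
  L <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  F <- matrix(stats::runif(G * k, 0.1, 1), G, k)
  s <- sqrt(mean(X) / mean(tcrossprod(L, F)))
  L <- L * s; F <- F * s

  loglik <- function(L, F) {
    mu <- pmax(tcrossprod(L, F), 1e-300)
    sum(X * log(mu) - mu) - sum(lgamma(X + 1))
  }
  em_step <- function(L, F) {
    mu <- pmax(tcrossprod(L, F), 1e-300)
    L <- L * ((X / mu) %*% F) / rep(colSums(F), each = n)
    mu <- pmax(tcrossprod(L, F), 1e-300)
    F <- F * (crossprod(X / mu, L)) / rep(colSums(L), each = G)
    list(L = pmax(L, 1e-15), F = pmax(F, 1e-15))
  }
  # one Newton coordinate-descent sweep over all columns of L then F;
  # per-sample (resp. per-gene) problems are independent, so a whole column
  # is an exact block of coordinate updates
  cd_step <- function(L, F) {
    for (t in seq_len(k)) {
      mu <- pmax(tcrossprod(L, F), 1e-300)
      R <- X / mu
      g <- sum(F[, t]) - R %*% F[, t, drop = FALSE]
      h <- (R / mu) %*% F[, t, drop = FALSE]^2
      step <- ifelse(h > 0, g / h, 0)
      L[, t] <- pmax(L[, t] - step, 1e-15)
    }
    for (t in seq_len(k)) {
      mu <- pmax(tcrossprod(L, F), 1e-300)
      R <- X / mu
      g <- sum(L[, t]) - crossprod(R, L[, t, drop = FALSE])
      h <- crossprod(R / mu, L[, t, drop = FALSE]^2)
      step <- ifelse(h > 0, g / h, 0)
      F[, t] <- pmax(F[, t] - step, 1e-15)
    }
    list(L = L, F = F)
  }

  trace <- numeric(em_iters + cd_iters + 1)
  trace[1] <- loglik(L, F)
  for (i in seq_len(em_iters)) {
    upd <- em_step(L, F); L <- upd$L; F <- upd$F
    trace[i + 1] <- loglik(L, F)
  }
  for (i in seq_len(cd_iters)) {
    prev <- trace[em_iters + i]
    upd <- cd_step(L, F)
    ll <- loglik(upd$L, upd$F)
    if (ll < prev - 1e-8) {            # Newton overshoot: fall back to EM
      upd <- em_step(L, F)
      ll <- loglik(upd$L, upd$F)
    }
    L <- upd$L; F <- upd$F
    trace[em_iters + i + 1] <- ll
  }
  list(L = L, F = F, loglik = trace[length(trace)], trace = trace)
}

#' Per-gene topic posteriors by Bayes' theorem
#'
#' posterior[g, t] = F[g, t] * prior[t] / sum_s F[g, s] * prior[s]: the
#' probability that a single transcript of gene g was emitted by topic t.
#' Genes with zero likelihood under every topic get the prior, with a
#' warning.
#'
#' @param fit a [fit_topics()] result (or a G x k factor matrix).
#' @param prior "uniform" (1/k each; 1/3 per topic when k = 3) or a k-vector
#'   summing to 1.
#' @return object of class "posterior_table": `posterior` (G x k, rows sum to
#'   1) and `prior`.
#' @export
topic_posteriors <- function(fit, prior = "uniform") {
  F <- if (inherits(fit, "topic_fit")) fit$F else as.matrix(fit)
  k <- ncol(F)
  if (identical(prior, "uniform")) prior <- rep(1 / k, k)
  if (length(prior) != k) stop("prior must have length k")
  if (any(prior < 0)) stop("prior probabilities must be non-negative")
  if (abs(sum(prior) - 1) > 1e-8) stop("prior must sum to 1")
  num <- sweep(F, 2, prior, "*")
  denom <- rowSums(num)
  flat <- denom == 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero likelihood under every topic set to the prior")
    num[flat, ] <- rep(prior, each = sum(flat))
    denom[flat] <- 1
  }
  post <- num / denom
  structure(list(posterior = post, prior = prior), class = "posterior_table")
}

#' Genes confidently assigned to one topic
#'
#' A gene belongs to topic t when its posterior p(topic|gene) exceeds
#' `cutoff`. Any cutoff >= 0.5 guarantees each gene appears in at most one
#' list.
#'
#' @param post a [topic_posteriors()] result.
#' @param cutoff posterior threshold in (1/k, 1], default 0.5.
#' @return named list of gene identifier vectors, one per topic.
#' @export
topic_gene_lists <- function(post, cutoff = 0.5) {
  P <- post$posterior
  k <- ncol(P)
  if (cutoff <= 1 / k || cutoff > 1)
    stop("cutoff must lie in (1/k, 1] for unambiguous assignment")
  out <- lapply(seq_len(k), function(t) rownames(P)[P[, t] > cutoff])
  names(out) <- colnames(P)
  out
}

#' Pairwise log2 fold changes between topic gene distributions
#'
#' @param fit a [fit_topics()] result.
#' @param pseudocount added to both factor values (default 1e-10; factor
#'   entries are probabilities, so this is far below one part in the gene
#'   universe).
#' @return G x k x k array: `[g, t, s]` is log2((F[g,t]+eps)/(F[g,s]+eps)).
#' @export
topic_de <- function(fit, pseudocount = 1e-10) {
  F <- fit$F
  G <- nrow(F); k <- ncol(F)
  lfc <- array(0, dim = c(G, k, k),
               dimnames = list(rownames(F), colnames(F), colnames(F)))
  lF <- log2(F + pseudocount)
  for (t in seq_len(k)) for (s in seq_len(k))
    lfc[, t, s] <- lF[, t] - lF[, s]
  lfc
}

#' @export
print.topic_fit <- function(x, ...) {
  cat("Topic model fit: k =", x$k, "topics,", nrow(x$L), "samples,",
      nrow(x$F), "genes\n")
  cat("  final log-likelihood:",
      format(x$loglik_trace[length(x$loglik_trace)], digits = 8), "\n")
  invisible(x)
}
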