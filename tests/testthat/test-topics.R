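# small planted fit shared within this file
small_topic_fit <- function() fixture("small_topic_fit", function() {
  co <- cohort_poisson()
  m <- co$sim$expression[, 1:120]
  fit_topics(m, k = 3, em_iters = 60, cd_iters = 40, seed = 2, n_restarts = 2)
})

test_that("k = 1 converges to the closed-form rank-1 Poisson solution", {
  set.seed(14)
  m <- matrix(rpois(20 * 8, outer(rexp(20, 1 / 50), runif(8, 0.5, 2))), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  m <- m[rowSums(m) > 0, ]
  fit <- suppressWarnings(fit_topics(m, k = 1, em_iters = 200, cd_iters = 50,
                                     seed = 1, n_restarts = 1))
  X <- t(m)
  mu_hat <- outer(rowSums(X), colSums(X)) / sum(X)   # rank-1 Poisson MLE
  ll_sat <- sum(X * log(pmax(mu_hat, 1e-300)) - mu_hat) - sum(lgamma(X + 1))
  expect_equal(fit$loglik_trace[length(fit$loglik_trace)], ll_sat,
               tolerance = 1e-6)
  expect_equal(unname(fit$L[, 1]), rep(1, nrow(X)))
})

test_that("the likelihood trace is non-decreasing and L/F are normalized", {
  fit <- small_topic_fit()
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(unname(rowSums(fit$L)), rep(1, nrow(fit$L)), tolerance = 1e-8)
  expect_equal(unname(colSums(fit$F)), rep(1, 3), tolerance = 1e-8)
  expect_true(all(fit$L >= 0) && all(fit$F >= 0))
})

test_that("planted loadings and factors are recovered after alignment", {
  co <- cohort_poisson()
  m <- co$sim$expression[, 1:200]
  fit <- fit_topics(m, k = 3, em_iters = 100, cd_iters = 100, seed = 5,
                    n_restarts = 2)
  Fstar <- t(co$ap$profiles / rowSums(co$ap$profiles))[rownames(fit$F), ]
  Lstar <- co$sim$truth$weights[rownames(fit$L), ]
  p <- match_components(-cor(fit$F, Fstar))
  expect_lt(mean(abs(fit$L[, p] - Lstar)), 0.05)
  for (j in 1:3) expect_gt(cor(fit$F[, p[j]], Fstar[, j]), 0.95)
})

test_that("near-pure samples take a dominant aligned loading", {
  co <- cohort_poisson()
  m <- co$sim$expression[, 1:200]
  fit <- fit_topics(m, k = 3, em_iters = 100, cd_iters = 100, seed = 5,
                    n_restarts = 2)
  Lstar <- co$sim$truth$weights[rownames(fit$L), ]
  p <- match_components(-cor(fit$L, Lstar))
  for (j in 1:3) {
    pure <- which(Lstar[, j] >= 0.9)
    if (length(pure)) expect_true(all(fit$L[pure, p[j]] > 0.8))
  }
})

test_that("tripling a sample's depth leaves its topic proportions unchanged", {
  co <- cohort_poisson()
  m <- co$sim$expression[, 1:80]
  m2 <- m; m2[, 7] <- 3 * m2[, 7]
  f1 <- fit_topics(m, k = 3, em_iters = 80, cd_iters = 40, seed = 3,
                   n_restarts = 1)
  f2 <- fit_topics(m2, k = 3, em_iters = 80, cd_iters = 40, seed = 3,
                   n_restarts = 1)
  p <- match_components(-cor(f2$F, f1$F))
  expect_lt(max(abs(f2$L[7, p] - f1$L[7, ])), 0.02)
})

test_that("relabeling samples permutes the fit correspondingly", {
  co <- cohort_poisson()
  m <- co$sim$expression[, 1:60]
  perm <- rev(seq_len(ncol(m)))
  f1 <- fit_topics(m, k = 3, em_iters = 80, cd_iters = 40, seed = 4,
                   n_restarts = 2)
  f2 <- fit_topics(m[, perm], k = 3, em_iters = 80, cd_iters = 40, seed = 4,
                   n_restarts = 2)
  p <- match_components(-cor(f2$F, f1$F))
  expect_lt(max(abs(f2$L[rownames(f1$L), p] - f1$L)), 0.02)
})

test_that("posteriors follow Bayes' rule in hand-checked cases", {
  F <- rbind(flat = c(0.001, 0.001, 0.001),
             prop = c(0.6, 0.3, 0.1) * 0.004,
             half = c(0.5, 0.5, 0) * 0.002)
  colnames(F) <- paste0("topic_", 1:3)
  post <- topic_posteriors(F, prior = "uniform")
  expect_equal(unname(post$posterior["flat", ]), rep(1 / 3, 3),
               tolerance = 1e-12)
  expect_equal(unname(post$posterior["prop", ]), c(0.6, 0.3, 0.1),
               tolerance = 1e-12)
  skew <- topic_posteriors(F, prior = c(0.8, 0.1, 0.1))
  expect_equal(unname(skew$posterior["half", ]), c(0.8 / 0.9, 0.1 / 0.9, 0),
               tolerance = 1e-12)
})

test_that("posteriors match independent evaluation on random factors", {
  set.seed(41)
  for (rep in 1:5) {
    k <- sample(2:5, 1); G <- 200
    F <- matrix(rexp(G * k), G, k,
                dimnames = list(sprintf("g%03d", 1:G), paste0("t", 1:k)))
    F <- sweep(F, 2, colSums(F), "/")
    prior <- rdirichlet(1, rep(2, k))[1, ]
    post <- topic_posteriors(F, prior = prior)
    # direct elementwise evaluation of the Bayes formula
    for (g in sample(G, 25)) {
      denom <- sum(F[g, ] * prior)
      expect_equal(unname(post$posterior[g, ]), unname(F[g, ] * prior / denom),
                   tolerance = 1e-12)
    }
    expect_equal(unname(rowSums(post$posterior)), rep(1, G),
                 tolerance = 1e-10)
  }
})

test_that("zero-likelihood genes fall back to the prior with a warning", {
  F <- rbind(ok = c(0.5, 0.5), zero = c(0, 0))
  colnames(F) <- c("t1", "t2")
  expect_warning(post <- topic_posteriors(F, prior = c(0.7, 0.3)),
                 "zero likelihood")
  expect_equal(unname(post$posterior["zero", ]), c(0.7, 0.3))
})

test_that("gene lists respect the posterior cutoff and are disjoint", {
  P <- rbind(g1 = c(0.6, 0.3, 0.1), g2 = c(0.45, 0.45, 0.10),
             g3 = c(0.2, 0.25, 0.55))
  colnames(P) <- paste0("topic_", 1:3)
  post <- structure(list(posterior = P, prior = rep(1 / 3, 3)),
                    class = "posterior_table")
  lists <- topic_gene_lists(post, cutoff = 0.5)
  expect_identical(lists$topic_1, "g1")
  expect_identical(lists$topic_3, "g3")
  expect_false("g2" %in% unlist(lists))
  expect_lte(max(table(unlist(lists))), 1)
  expect_error(topic_gene_lists(post, cutoff = 0.2), "cutoff")
})

test_that("posterior gene lists match the inequality on random posteriors", {
  set.seed(47)
  P <- rdirichlet(1000, c(1, 1, 1))
  rownames(P) <- sprintf("g%04d", 1:1000)
  colnames(P) <- paste0("topic_", 1:3)
  post <- structure(list(posterior = P, prior = rep(1 / 3, 3)),
                    class = "posterior_table")
  lists <- topic_gene_lists(post, cutoff = 0.5)
  for (t in 1:3)
    expect_identical(lists[[t]], rownames(P)[P[, t] > 0.5])
})

test_that("topic gene lists recover the planted marker blocks", {
  co <- cohort_poisson()
  fit <- small_topic_fit()
  Fstar <- t(co$ap$profiles / rowSums(co$ap$profiles))[rownames(fit$F), ]
  p <- match_components(-cor(fit$F, Fstar))
  lists <- topic_gene_lists(topic_posteriors(fit), cutoff = 0.5)
  for (j in 1:3) {
    truth <- intersect(co$ap$marker_sets[[j]], rownames(fit$F))
    expect_gte(length(intersect(lists[[p[j]]], truth)) / length(truth), 0.9)
    for (o in setdiff(1:3, j))
      expect_length(intersect(lists[[p[o]]], truth), 0)
  }
})

test_that("pairwise topic fold changes are antisymmetric and exact", {
  fit <- small_topic_fit()
  lfc <- topic_de(fit)
  expect_equal(lfc[, 1, 2], -lfc[, 2, 1], tolerance = 1e-12)
  expect_equal(unname(lfc[, 2, 2]), rep(0, dim(lfc)[1]))
  F <- cbind(t1 = c(4e-4), t2 = c(1e-4))
  rownames(F) <- "g"
  fit2 <- list(F = F)
  expect_equal(unname(topic_de(structure(fit2, class = "topic_fit"))[1, 1, 2]),
               2, tolerance = 1e-5)
})

test_that("non-integer input is rescaled to counts with a message", {
  co <- cohort_noiseless()
  m <- co$sim$expression[, 1:40]           # continuous mixture values
  expect_message(fit <- fit_topics(m, k = 3, em_iters = 20, cd_iters = 10,
                                   seed = 1, n_restarts = 1),
                 "rescaled to total")
  expect_equal(unname(rowSums(fit$L)), rep(1, 40), tolerance = 1e-8)
})
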