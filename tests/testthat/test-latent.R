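test_that("collinear data loads entirely on the first component", {
  x <- seq(1, 10)
  m <- rbind(g1 = x, g2 = 2 * x)
  colnames(m) <- paste0("s", seq_along(x))
  emb <- pca_embed(m, d = 1)
  expect_equal(emb$explained_variance_ratio[1], 1, tolerance = 1e-12)
})

test_that("a noiseless 3-archetype cohort is exactly rank 2 after centering", {
  co <- cohort_noiseless()
  emb <- pca_embed(co$sim$expression, d = 3)
  expect_lt(emb$explained_variance_ratio[3], 1e-9)
})

test_that("full-rank embeddings reconstruct the input", {
  set.seed(3)
  m <- matrix(rexp(5 * 10), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  emb <- pca_embed(m, d = 5)
  rec <- t(sweep(emb$coords %*% t(emb$loadings), 2, emb$center, "+"))
  expect_equal(rec, m, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("explained variance ratios are non-increasing and sum below one", {
  co <- cohort_poisson()
  emb <- pca_embed(co$sim$expression, d = 4)
  expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-12)
})

test_that("a simplex over its own vertices is recovered to high precision", {
  V <- rbind(c(0, 0), c(4, 0), c(1, 3))
  X <- V[rep(1:3, each = 10), ]
  rownames(X) <- sprintf("S%02d", 1:30)
  emb <- list(coords = X)
  fit <- fit_simplex(emb, k = 3, seed = 2)
  expect_lt(max(vertex_errors(fit$vertices, V)), 1e-6)
  expect_equal(fit$fit_diagnostics$containment_fraction, 1)
})

test_that("dense noiseless mixtures recover the generating vertices", {
  V <- rbind(c(-2, -1), c(3, 0), c(0, 4))
  set.seed(6)
  W <- rdirichlet(500, c(1, 1, 1))
  X <- W %*% V
  rownames(X) <- sprintf("S%03d", 1:500)
  fit <- fit_simplex(list(coords = X), seed = 4)
  diam <- max(dist(V))
  expect_lt(max(vertex_errors(fit$vertices, V)) / diam, 0.02)
})

test_that("simplex fitting is rotation equivariant", {
  V <- rbind(c(-2, -1), c(3, 0), c(0, 4))
  set.seed(9)
  W <- rdirichlet(200, c(1, 1, 1))
  X <- W %*% V
  rownames(X) <- sprintf("S%03d", 1:200)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  f1 <- fit_simplex(list(coords = X), seed = 4)
  f2 <- fit_simplex(list(coords = X %*% R), seed = 4)
  rotated <- f1$vertices %*% R
  # documented tolerance: the optimum sits on a hinge kink, so independently
  # restarted optimizations agree to ~1e-4 of the cloud scale, not exactly
  expect_lt(max(vertex_errors(f2$vertices, rotated)), 1e-3)
})

test_that("shrinking the cloud toward its centroid shrinks the simplex", {
  co <- cohort_noiseless()
  emb <- pca_embed(co$sim$expression, d = 2)
  f1 <- fit_simplex(emb, seed = 2)
  ctr <- colMeans(emb$coords)
  shrunk <- sweep(sweep(emb$coords, 2, ctr, "-") * 0.5, 2, ctr, "+")
  f2 <- fit_simplex(list(coords = shrunk), seed = 2)
  expect_lt(f2$fit_diagnostics$volume, f1$fit_diagnostics$volume)
})

test_that("the fit matches exhaustive search over data-point triangles", {
  # points inside a triangle whose vertices are in the data: the exhaustive
  # minimum over enclosing data triangles is the true triangle
  V <- rbind(c(0, 0), c(5, 1), c(2, 4))
  set.seed(12)
  W <- rdirichlet(9, c(2, 2, 2))
  X <- rbind(V, W %*% V)
  rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  combs <- utils::combn(nrow(X), 3)
  best <- Inf
  for (i in seq_len(ncol(combs))) {
    tri <- X[combs[, i], ]
    E <- sweep(tri[-1, ], 2, tri[1, ], "-")
    if (abs(det(E)) < 1e-9) next
    B <- barycentric_coords(X, tri)
    if (min(B) >= -1e-9) best <- min(best, simplex_volume(tri))
  }
  fit <- fit_simplex(list(coords = X), seed = 3)
  expect_equal(fit$fit_diagnostics$volume, best, tolerance = 1e-3)
  expect_lte(fit$fit_diagnostics$volume, best * (1 + 1e-3))
})

test_that("rank-deficient embeddings are refused with advice", {
  X <- cbind(seq_len(20), 2 * seq_len(20))
  rownames(X) <- sprintf("S%02d", 1:20)
  expect_error(fit_simplex(list(coords = X), seed = 1), "lower d")
})

test_that("back-projection satisfies the reconstruction identities", {
  co <- cohort_noiseless()
  emb <- pca_embed(co$sim$expression, d = 2)
  at_origin <- backproject(rep(0, 2), emb)
  expect_equal(as.numeric(at_origin), unname(pmax(emb$center, 0)),
               tolerance = 1e-12)
  # a vertex placed on a sample reproduces that sample (rank-2 data, d = 2)
  prof <- backproject(emb$coords[5, ], emb)
  expect_equal(as.numeric(prof), unname(co$sim$expression[, 5]),
               tolerance = 1e-6)
})

test_that("back-projected archetypes correlate with the true profiles", {
  co <- cohort_noiseless()
  emb <- pca_embed(co$sim$expression, d = 2)
  fit <- fit_simplex(emb, seed = 2)
  Vtrue <- true_vertices_in(emb, co$ap$profiles)
  cost <- as.matrix(dist(rbind(fit$vertices, Vtrue)))[1:3, 4:6]
  p <- match_components(cost)
  for (j in 1:3)
    expect_gt(cor(fit$gene_profiles[p[j], ], co$ap$profiles[j, ]), 0.95)
})

test_that("archetype marker rule matches its defining inequality", {
  prof <- rbind(a1 = c(40, 5), a2 = c(8, 5), a3 = c(8, 5))
  colnames(prof) <- c("gA", "gB")
  out <- archetype_markers(prof, fc_threshold = 2, pseudocount = 1)
  expect_identical(out$a1, "gA")            # log2(41/9) = 2.19 > 2
  expect_identical(out$a2, character(0))
  same <- matrix(3, 3, 4, dimnames = list(paste0("a", 1:3), paste0("g", 1:4)))
  expect_true(all(lengths(archetype_markers(same)) == 0))
})

test_that("marker rule agrees with brute force on random profiles", {
  set.seed(31)
  prof <- matrix(rexp(3 * 1000, rate = 1 / 20), 3, 1000,
                 dimnames = list(paste0("a", 1:3), sprintf("g%04d", 1:1000)))
  out <- archetype_markers(prof, fc_threshold = 2, pseudocount = 1)
  for (t in 1:3) {
    manual <- character(0)
    for (g in colnames(prof)) {
      ok <- TRUE
      for (s in setdiff(1:3, t))
        if (!(log2((prof[t, g] + 1) / (prof[s, g] + 1)) > 2)) ok <- FALSE
      if (ok) manual <- c(manual, g)
    }
    expect_identical(out[[t]], manual)
  }
})

test_that("planted marker blocks are recovered without cross-assignment", {
  co <- cohort_noiseless()
  emb <- pca_embed(co$sim$expression, d = 2)
  fit <- fit_simplex(emb, seed = 2)
  Vtrue <- true_vertices_in(emb, co$ap$profiles)
  p <- match_components(as.matrix(dist(rbind(fit$vertices, Vtrue)))[1:3, 4:6])
  lists <- archetype_markers(fit)
  for (j in 1:3) {
    truth <- co$ap$marker_sets[[j]]
    found <- lists[[p[j]]]
    expect_gte(length(intersect(found, truth)) / length(truth), 0.9)
    for (other in setdiff(1:3, j))
      expect_length(intersect(lists[[p[other]]], truth), 0)
  }
})

test_that("hypergeometric scoring matches the closed form and labels sets", {
  universe <- sprintf("g%04d", 1:1000)
  set10 <- universe[1:10]
  lib <- list(lineage_A = set10, lineage_B = universe[101:130])
  sc <- score_markers(list(arch1 = set10), lib, universe)
  p_closed <- choose(10, 10) * choose(990, 0) / choose(1000, 10)
  expect_equal(sc$enrichment$p_value[1], p_closed, tolerance = 1e-12)
  expect_identical(unname(sc$labels["arch1"]), "lineage_A")
})

test_that("disjoint lists are unassigned and planted blocks label correctly", {
  co <- cohort_noiseless()
  universe <- rownames(co$sim$expression)
  lib <- co$ap$marker_sets
  sc <- score_markers(list(a = c("zzz1", "zzz2"), b = character(0)),
                      lib, universe)
  expect_identical(unname(sc$labels), c("unassigned", "unassigned"))

  emb <- pca_embed(co$sim$expression, d = 2)
  fit <- fit_simplex(emb, seed = 2)
  labeled <- label_archetypes(fit, lib, universe)
  expect_setequal(labeled$labels, names(lib))
})
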