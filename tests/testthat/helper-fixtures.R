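# Shared fixtures, built once per test run and cached in this environment.
# Everything is generated in code under fixed seeds; no files are read.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# mid-sized 3-archetype cohort with planted marker blocks, noiseless
cohort_noiseless <- function() fixture("cohort_noiseless", function() {
  ap <- make_archetype_profiles(k = 3, n_genes = 300, block_size = 15,
                                depth = 1e4, seed = 42)
  tr <- mixture_truth(ap$profiles, dirichlet_alpha = c(1, 1, 1),
                      noise_model = "none", seed = 19)
  sim <- simulate_bulk_cohort(tr, n_samples = 300)
  list(ap = ap, sim = sim)
})

# same archetypes with Poisson counts
cohort_poisson <- function() fixture("cohort_poisson", function() {
  ap <- cohort_noiseless()$ap
  tr <- mixture_truth(ap$profiles, dirichlet_alpha = c(1, 1, 1),
                      noise_model = "poisson", seed = 19)
  sim <- simulate_bulk_cohort(tr, n_samples = 300)
  list(ap = ap, sim = sim)
})

# small labeled reference with disjoint type supports plus matched bulk
reference_small <- function() fixture("reference_small", function() {
  rt <- make_reference_truth(n_types = 3, cells_per_type = 40, n_genes = 150,
                             disjoint_support = TRUE, noise_model = "none",
                             seed = 7)
  simulate_reference_and_bulk(rt)
})

# project true archetype gene profiles into a fitted embedding
true_vertices_in <- function(embedding, profiles) {
  sweep(profiles, 2, embedding$center, "-") %*% embedding$loadings
}

# align fitted vertices to true vertices, return per-vertex distances
vertex_errors <- function(fitted, truth) {
  cost <- as.matrix(stats::dist(rbind(fitted, truth)))[
    seq_len(nrow(fitted)), nrow(fitted) + seq_len(nrow(truth))]
  p <- match_components(cost)
  vapply(seq_len(nrow(truth)), function(j)
    sqrt(sum((fitted[p[j], ] - truth[j, ])^2)), numeric(1))
}
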