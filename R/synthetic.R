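#' Ground-truth description of a convex-mixture bulk cohort
#'
#' Bundles everything needed to simulate bulk expression profiles as convex
#' mixtures of k archetypal gene profiles: the archetype profiles themselves,
#' optional fixed mixture weights (otherwise drawn from a Dirichlet), the
#' Dirichlet concentration parameters, a noise model, and a seed.
#'
#' @param archetype_profiles k x G non-negative matrix of expected expression,
#'   one row per archetype, columns named by gene.
#' @param weights optional n x k convex mixture weights (rows sum to 1). When
#'   NULL, [simulate_bulk_cohort()] draws them from the Dirichlet.
#' @param dirichlet_alpha k positive concentration parameters.
#' @param noise_model one of "poisson" (counts), "lognormal" (multiplicative,
#'   microarray-like), "none".
#' @param dispersion log-sd of the lognormal noise (ignored otherwise).
#' @param seed integer seed controlling all randomness downstream.
#' @return object of class "mixture_truth".
#' @export
mixture_truth <- function(archetype_profiles, weights = NULL,
                          dirichlet_alpha = rep(1, nrow(archetype_profiles)),
                          noise_model = c("poisson", "lognormal", "none"),
                          dispersion = 0.2, seed = 1L) {
  noise_model <- match.arg(noise_model)
  k <- nrow(archetype_profiles)
  G <- ncol(archetype_profiles)
  if (k < 2) stop("need at least k = 2 archetypes")
  if (G < k) stop("need at least as many genes as archetypes (G >= k)")
  if (any(archetype_profiles < 0)) stop("archetype profiles must be non-negative")
  if (length(dirichlet_alpha) != k) stop("dirichlet_alpha must have length k")
  if (any(dirichlet_alpha <= 0)) stop("Dirichlet concentration parameters must be positive")
  if (is.null(colnames(archetype_profiles)))
    colnames(archetype_profiles) <- sprintf("gene_%04d", seq_len(G))
  if (is.null(rownames(archetype_profiles)))
    rownames(archetype_profiles) <- sprintf("archetype_%d", seq_len(k))
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (ncol(weights) != k) stop("weights must have k columns")
    if (any(weights < 0) || any(abs(rowSums(weights) - 1) > 1e-12))
      stop("weight rows must be non-negative and sum to 1")
  }
  structure(list(archetype_profiles = archetype_profiles, weights = weights,
                 dirichlet_alpha = dirichlet_alpha, noise_model = noise_model,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "mixture_truth")
}

#' Draw sparse archetype gene profiles with exclusive marker blocks
#'
#' Each archetype receives a block of `block_size` genes expressed only by it
#' (its markers, at a high level), on top of a shared sparse gamma background.
#' Profiles are rescaled so each archetype's expected library size equals
#' `depth`, which makes Poisson noise behave like sequencing counts at that
#' depth.
#'
#' @param k number of archetypes.
#' @param n_genes total number of genes G (must exceed k * block_size).
#' @param block_size genes per exclusive marker block.
#' @param depth expected total expression per archetype profile.
#' @param marker_boost expected marker level relative to the mean background
#'   gene level.
#' @param sparsity fraction of background entries set to zero.
#' @param seed integer seed.
#' @return list with `profiles` (k x G) and `marker_sets` (named list of the
#'   planted per-archetype marker genes, GMT-ready).
#' @export
make_archetype_profiles <- function(k = 3, n_genes = 500, block_size = 20,
                                    depth = 1e4, marker_boost = 12,
                                    sparsity = 0.3, seed = 1L) {
  if (n_genes < k * block_size + k)
    stop("n_genes too small for k marker blocks of this size")
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    prof <- matrix(stats::rgamma(k * n_genes, shape = 0.8, rate = 1),
                   nrow = k, dimnames = list(sprintf("archetype_%d", seq_len(k)), genes))
    prof[matrix(stats::runif(k * n_genes) < sparsity, k)] <- 0
    marker_sets <- vector("list", k)
    for (t in seq_len(k)) {
      idx <- ((t - 1) * block_size + 1):(t * block_size)
      prof[, idx] <- 0                        # exclusive: silent in the others
      prof[t, idx] <- stats::rgamma(block_size, shape = 4, rate = 1) *
        marker_boost * 0.8 / 4
      marker_sets[[t]] <- genes[idx]
    }
    names(marker_sets) <- rownames(prof)
    prof <- prof / rowSums(prof) * depth
    list(profiles = prof, marker_sets = marker_sets)
  })
}

#' Simulate a bulk cohort of convex archetype mixtures
#'
#' Sample i has expected expression `sum_t weights[i, t] * profile_t`; noise is
#' then applied per the truth's noise model. The returned truth records the
#' realized weights, so downstream recovery can be scored against them.
#'
#' @param truth a [mixture_truth()] object.
#' @param n_samples number of bulk samples; required when `truth$weights` is
#'   NULL, ignored otherwise.
#' @return list with `expression` (G x n matrix, genes in rows) and `truth`
#'   (input truth with realized `weights`).
#' @export
simulate_bulk_cohort <- function(truth, n_samples = NULL) {
  stopifnot(inherits(truth, "mixture_truth"))
  prof <- truth$archetype_profiles
  k <- nrow(prof)
  with_seed(truth$seed, {
    W <- truth$weights
    if (is.null(W)) {
      if (is.null(n_samples)) stop("n_samples required when truth carries no weights")
      W <- rdirichlet(n_samples, truth$dirichlet_alpha)
    }
    n <- nrow(W)
    mu <- W %*% prof                        # n x G expected expression
    x <- switch(truth$noise_model,
      none      = mu,
      poisson   = matrix(stats::rpois(length(mu), mu), nrow(mu)),
      lognormal = mu * matrix(exp(stats::rnorm(length(mu), -truth$dispersion^2 / 2,
                                               truth$dispersion)), nrow(mu)))
    rownames(W) <- rownames(x) <- sprintf("S%03d", seq_len(n))
    colnames(W) <- rownames(prof)
    colnames(x) <- colnames(prof)
    truth$weights <- W
    expr <- t(x)                            # genes x samples
    validate_expression(expr)
    list(expression = expr, truth = truth)
  })
}

#' Ground-truth description of a single-cell reference and matched bulk
#'
#' @param cell_profiles C x G non-negative matrix of per-cell expected
#'   expression.
#' @param cell_type_labels length-C character/factor of cell-type labels.
#' @param embedding C x 2 cell-state coordinates (generated as Gaussian
#'   clusters per type by [make_reference_truth()]).
#' @param bulk_composition n x T convex weights over the T types for each
#'   synthetic bulk sample.
#' @param noise_model "poisson" or "none", applied to the bulk samples.
#' @param seed integer seed.
#' @return object of class "reference_truth".
#' @export
reference_truth <- function(cell_profiles, cell_type_labels, embedding,
                            bulk_composition,
                            noise_model = c("none", "poisson"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  labels <- as.character(cell_type_labels)
  types <- sort(unique(labels))
  if (nrow(cell_profiles) != length(labels)) stop("one label per cell required")
  if (any(cell_profiles < 0)) stop("cell profiles must be non-negative")
  if (nrow(embedding) != length(labels) || ncol(embedding) != 2)
    stop("embedding must be C x 2")
  bulk_composition <- as.matrix(bulk_composition)
  if (ncol(bulk_composition) != length(types))
    stop("bulk_composition needs one column per cell type")
  if (is.null(colnames(bulk_composition))) colnames(bulk_composition) <- types
  if (any(bulk_composition < 0) ||
      any(abs(rowSums(bulk_composition) - 1) > 1e-12))
    stop("bulk_composition rows must be convex (non-negative, sum to 1)")
  missing <- setdiff(colnames(bulk_composition), types)
  if (length(missing)) stop("composition refers to types with zero cells: ",
                            paste(missing, collapse = ", "))
  structure(list(cell_profiles = cell_profiles, cell_type_labels = labels,
                 embedding = embedding, bulk_composition = bulk_composition,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "reference_truth")
}

#' Build a labeled synthetic single-cell reference with a 2D embedding
#'
#' Types get gamma-distributed mean profiles; with `disjoint_support = TRUE`
#' each type expresses a private gene block only (orthogonal supports, which
#' makes deconvolution exactly solvable and is the benchmark configuration).
#' Cells are gamma-perturbed copies of their type mean. The embedding places
#' each type as a Gaussian cluster around a vertex of a regular polygon, which
#' is all the smoothing step of deconvolution needs (a neighborhood structure
#' in which same-type cells are close).
#'
#' @param n_types number of cell types T.
#' @param cells_per_type cells per type (C = T * cells_per_type).
#' @param n_genes gene count G.
#' @param depth expected total expression of a type mean profile.
#' @param disjoint_support give types non-overlapping expressed gene sets.
#' @param bulk_composition optional n x T convex matrix; default is a small
#'   cohort spanning pure types and mixtures.
#' @param noise_model bulk noise, "none" or "poisson".
#' @param cluster_sd spread of each type's Gaussian cluster in the embedding.
#' @param seed integer seed.
#' @return object of class "reference_truth".
#' @export
make_reference_truth <- function(n_types = 3, cells_per_type = 100,
                                 n_genes = 300, depth = 1e4,
                                 disjoint_support = TRUE,
                                 bulk_composition = NULL,
                                 noise_model = c("none", "poisson"),
                                 cluster_sd = 0.6, seed = 1L) {
  noise_model <- match.arg(noise_model)
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    types <- sprintf("type%d", seq_len(n_types))
    means <- matrix(0, n_types, n_genes, dimnames = list(types, genes))
    if (disjoint_support) {
      block <- floor(n_genes / n_types)
      for (t in seq_len(n_types)) {
        idx <- ((t - 1) * block + 1):(t * block)
        means[t, idx] <- stats::rgamma(length(idx), shape = 1, rate = 1)
      }
    } else {
      means[] <- stats::rgamma(n_types * n_genes, shape = 0.8, rate = 1)
    }
    means <- means / rowSums(means) * depth
    C <- n_types * cells_per_type
    labels <- rep(types, each = cells_per_type)
    prof <- means[labels, , drop = FALSE] *
      matrix(stats::rgamma(C * n_genes, shape = 20, rate = 20), C)
    rownames(prof) <- sprintf("cell_%04d", seq_len(C))
    centers <- 10 * cbind(cos(2 * pi * seq_len(n_types) / n_types),
                          sin(2 * pi * seq_len(n_types) / n_types))
    emb <- centers[match(labels, types), ] +
      matrix(stats::rnorm(2 * C, sd = cluster_sd), C)
    rownames(emb) <- rownames(prof)
    colnames(emb) <- c("dim1", "dim2")
    if (is.null(bulk_composition)) {
      pure <- diag(n_types)
      mixed <- rdirichlet(3 * n_types, rep(2, n_types))
      bulk_composition <- rbind(pure, mixed)
    }
    reference_truth(prof, labels, emb, bulk_composition,
                    noise_model = noise_model, seed = seed)
  })
}

#' Simulate a single-cell reference and bulk samples mixed from it
#'
#' Bulk sample i has expected profile `sum_t composition[i, t] * mean profile
#' of type t` (type means computed over the emitted reference cells), so the
#' reference handed to deconvolution is exactly the one that generated the
#' bulk.
#'
#' @param truth a [reference_truth()] object.
#' @return list: `reference` (G x C matrix), `labels` (named character),
#'   `embedding` (C x 2), `bulk` (G x n), `truth`.
#' @export
simulate_reference_and_bulk <- function(truth) {
  stopifnot(inherits(truth, "reference_truth"))
  with_seed(truth$seed + 1L, {
    prof <- truth$cell_profiles                 # C x G
    labels <- truth$cell_type_labels
    types <- colnames(truth$bulk_composition)
    type_means <- t(vapply(types,
      function(t) colMeans(prof[labels == t, , drop = FALSE]),
      numeric(ncol(prof))))
    mu <- truth$bulk_composition %*% type_means # n x G
    bulk <- switch(truth$noise_model,
      none    = mu,
      poisson = matrix(stats::rpois(length(mu), mu), nrow(mu)))
    rownames(bulk) <- sprintf("bulk_%03d", seq_len(nrow(bulk)))
    colnames(bulk) <- colnames(prof)
    names(labels) <- rownames(prof)
    list(reference = t(prof), labels = labels, embedding = truth$embedding,
         bulk = t(bulk), truth = truth)
  })
}

#' Write a synthetic cohort to disk as plain-text files
#'
#' Emits the expression TSV, marker-block GMT (when provided), and a truth
#' JSON holding weights/compositions and the seed.
#'
#' @param sim output of [simulate_bulk_cohort()].
#' @param dir output directory (created if needed).
#' @param marker_sets optional named list of planted marker genes.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(sim, dir, marker_sets = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  if (!is.null(marker_sets))
    write_gmt(marker_sets, file.path(dir, "marker_blocks.gmt"))
  truth <- sim$truth
  jsonlite::write_json(
    list(weights = truth$weights, dirichlet_alpha = truth$dirichlet_alpha,
         noise_model = truth$noise_model, seed = truth$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
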