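#' Cross-method consistency of the three characterizations
#'
#' The three views of a cohort — proximity to each archetype in latent space,
#' topic loadings, and deconvolved cell-type proportions — describe the same
#' underlying composition, so after aligning components they should agree
#' sample by sample. Components are aligned as an assignment problem:
#' archetypes map to the topics whose loadings correlate best with negative
#' archetype distance, and cell types are grouped to the topic their
#' proportion correlates with most (a user mapping can override the
#' grouping). For each aligned triple the report carries the Pearson
#' correlation between (-distance to archetype) and topic loading, and
#' between topic loading and grouped cell-type proportion. Constant columns
#' yield NA correlations.
#'
#' @param archetypes a [fit_simplex()] result.
#' @param embedding the [pca_embed()] result the simplex was fitted in.
#' @param topic_fit a [fit_topics()] result on the same samples.
#' @param type_proportions samples x types matrix (from [cpm_deconvolve()]),
#'   or NULL to report archetype-topic consistency only.
#' @param type_groups optional named list mapping group names to character
#'   vectors of cell types; defaults to maximal-correlation grouping.
#' @return object of class "consistency_report": `per_sample` data.frame
#'   (distances, loadings, grouped proportions), `alignment` (archetype ->
#'   topic -> type group), `correlations` data.frame.
#' @export
consistency_metrics <- function(archetypes, embedding, topic_fit,
                                type_proportions = NULL, type_groups = NULL) {
  V <- archetypes$vertices
  X <- embedding$coords
  k <- nrow(V)
  D <- vapply(seq_len(k), function(t)
    sqrt(rowSums(sweep(X, 2, V[t, ], "-")^2)), numeric(nrow(X)))
  colnames(D) <- rownames(V)
  L <- topic_fit$L
  common <- intersect(rownames(X), rownames(L))
  if (length(common) < 3) stop("views share too few samples")
  D <- D[common, , drop = FALSE]; L <- L[common, , drop = FALSE]

  safe_cor <- function(a, b)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)

  if (ncol(L) != k) stop("topic count must match archetype count for alignment")
  cost <- -vapply(seq_len(k), function(t) vapply(seq_len(k), function(a)
    safe_cor(-D[, a], L[, t]) %||% NA_real_, numeric(1)), numeric(k))
  cost[is.na(cost)] <- 1                       # NA correlation: worst cost
  perm <- match_components(t(cost))            # topic perm[a] <-> archetype a
  arch_topic_cor <- vapply(seq_len(k), function(a)
    safe_cor(-D[, a], L[, perm[a]]), numeric(1))

  alignment <- data.frame(archetype = rownames(V),
                          topic = colnames(L)[perm],
                          stringsAsFactors = FALSE)
  correlations <- data.frame(alignment,
                             archetype_topic_cor = arch_topic_cor,
                             topic_type_cor = NA_real_,
                             type_group = NA_character_,
                             stringsAsFactors = FALSE)
  per_sample <- data.frame(sample = common, -D[, , drop = FALSE],
                           L[, , drop = FALSE], check.names = FALSE)
  colnames(per_sample) <- c("sample", paste0("neg_dist_", rownames(V)),
                            paste0("loading_", colnames(L)))

  if (!is.null(type_proportions)) {
    P <- type_proportions[common, , drop = FALSE]
    if (is.null(type_groups)) {
      # group each type with the topic its proportion tracks best
      best <- apply(P, 2, function(p) {
        cors <- vapply(seq_len(k), function(t) safe_cor(p, L[, t]), numeric(1))
        if (all(is.na(cors))) NA_integer_ else which.max(cors)
      })
      type_groups <- lapply(seq_len(k), function(t)
        colnames(P)[!is.na(best) & best == t])
      names(type_groups) <- colnames(L)
    }
    GP <- vapply(names(type_groups), function(g) {
      members <- intersect(type_groups[[g]], colnames(P))
      if (length(members) == 0) rep(0, nrow(P))
      else rowSums(P[, members, drop = FALSE])
    }, numeric(nrow(P)))
    for (a in seq_len(k)) {
      topic <- colnames(L)[perm[a]]
      if (topic %in% colnames(GP)) {
        correlations$topic_type_cor[a] <- safe_cor(L[, perm[a]], GP[, topic])
        correlations$type_group[a] <-
          paste(type_groups[[topic]], collapse = "+")
      }
    }
    per_sample <- cbind(per_sample, GP)
  }

  structure(list(per_sample = per_sample, alignment = alignment,
                 correlations = correlations, type_groups = type_groups),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Consistency report over", nrow(x$per_sample), "samples\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Executes preprocess -> PCA -> simplex archetypes -> topic model ->
#' (optional) deconvolution -> consistency report, writing every stage output
#' and a manifest (parameters plus md5 of each written file) under
#' `output_dir`. Reruns with the same configuration produce byte-identical
#' outputs. A stage failure aborts with the stage name; files already written
#' are moved under a `failed/` prefix.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized blocks: `expression` (path or matrix), `probe_map`
#'   (optional path), `standardize` (mode), `outliers`
#'   (list: enabled, n_pcs, z_cut), `archetypes` (d, k, seed,
#'   penalty_weight), `markers` (GMT path or named list), `topics` (k,
#'   em_iters, cd_iters, seed), `deconvolution` (reference, labels, embedding
#'   — paths or objects — plus model_size, min_selection, neighborhood_size,
#'   seed), `output_dir`.
#' @return list with all stage objects (`matrix`, `embedding`, `archetypes`,
#'   `topics`, `deconvolution`, `report`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$output_dir %||% stop("config needs output_dir")
  d <- cfg$archetypes$d %||% 2
  k_arch <- cfg$archetypes$k %||% (d + 1)
  if (k_arch != d + 1)
    stop("config invalid: archetypes require k = d + 1 (got k = ", k_arch,
         ", d = ", d, ")")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fail_dir <- file.path(out_dir, "failed")
      dir.create(fail_dir, showWarnings = FALSE)
      for (f in written[file.exists(written)])
        file.rename(f, file.path(fail_dir, basename(f)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  m <- stage("preprocess", {
    m <- cfg$expression
    if (is.character(m)) m <- read_expression(m)
    validate_expression(m)
    if (!is.null(cfg$probe_map)) {
      pm <- if (is.character(cfg$probe_map)) read_probe_map(cfg$probe_map)
            else cfg$probe_map
      m <- collapse_probes(m, pm)
    }
    m <- standardize(m, cfg$standardize %||% "none")
    m
  })

  emb_full <- stage("pca", pca_embed(m, d = min(max(3, d), ncol(m) - 1)))
  m <- stage("outliers", {
    oc <- cfg$outliers
    if (!is.null(oc) && isTRUE(oc$enabled)) {
      flagged <- flag_outliers(emb_full, n_pcs = oc$n_pcs %||% 3,
                               z_cut = oc$z_cut %||% 4)
      if (length(flagged)) {
        message("removing ", length(flagged), " outlier sample(s): ",
                paste(flagged, collapse = ", "))
        m <- m[, setdiff(colnames(m), flagged), drop = FALSE]
      }
    }
    m
  })

  emb <- stage("pca", pca_embed(m, d = d))
  arch <- stage("archetypes", {
    a <- fit_simplex(emb, k = k_arch,
                     penalty_weight = cfg$archetypes$penalty_weight %||% 10,
                     seed = cfg$archetypes$seed %||% 1L)
    if (!is.null(cfg$markers)) {
      lib <- if (is.character(cfg$markers)) read_gmt(cfg$markers) else cfg$markers
      a <- label_archetypes(a, lib, rownames(m))
    }
    a
  })
  utils::write.table(
    data.frame(archetype = rownames(arch$vertices), arch$vertices,
               label = arch$labels, check.names = FALSE),
    emit(file.path(out_dir, "archetypes.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)

  topics <- stage("topics", fit_topics(
    m, k = cfg$topics$k %||% k_arch,
    em_iters = cfg$topics$em_iters %||% 100,
    cd_iters = cfg$topics$cd_iters %||% 100,
    seed = cfg$topics$seed %||% 1L,
    n_restarts = cfg$topics$n_restarts %||% 3))
  write_expression(t(topics$L), emit(file.path(out_dir, "topic_loadings.tsv")),
                   id_col = "topic")
  write_expression(topics$F, emit(file.path(out_dir, "topic_factors.tsv")))
  post <- topic_posteriors(topics)
  write_expression(post$posterior,
                   emit(file.path(out_dir, "topic_posteriors.tsv")))

  deconv <- NULL
  if (!is.null(cfg$deconvolution)) {
    deconv <- stage("deconvolution", {
      dc <- cfg$deconvolution
      ref <- if (is.character(dc$reference)) read_reference_matrix(
        dc$reference, dc$reference_genes, dc$reference_cells) else dc$reference
      labels <- if (is.character(dc$labels) && length(dc$labels) == 1)
        utils::read.table(dc$labels, header = TRUE, sep = "\t")[[2]]
        else dc$labels
      cs <- if (is.character(dc$embedding)) as.matrix(utils::read.table(
        dc$embedding, header = TRUE, sep = "\t", row.names = 1)) else dc$embedding
      cpm_deconvolve(m, ref, labels, cs,
                     model_size = dc$model_size %||% 50,
                     min_selection = dc$min_selection %||% 5,
                     neighborhood_size = dc$neighborhood_size %||% 10,
                     seed = dc$seed %||% 1L)
    })
    write_expression(t(deconv$cell_abundance),
                     emit(file.path(out_dir, "cell_abundance.tsv")),
                     id_col = "cell_id")
    write_expression(t(deconv$type_proportions),
                     emit(file.path(out_dir, "type_proportions.tsv")),
                     id_col = "cell_type")
  }

  report <- stage("consistency", consistency_metrics(
    arch, emb, topics,
    type_proportions = if (!is.null(deconv)) deconv$type_proportions,
    type_groups = cfg$type_groups))
  utils::write.table(report$per_sample,
                     emit(file.path(out_dir, "consistency_per_sample.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$correlations,
                     emit(file.path(out_dir, "consistency_correlations.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("expression", "markers",
                                           "deconvolution"))],
    files = as.list(tools::md5sum(sort(written))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(matrix = m, embedding = emb, archetypes = arch,
                 topics = topics, deconvolution = deconv, report = report,
                 manifest = manifest))
}
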