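# End-to-end driver: distances -> weights -> OP -> ensembles -> pairwise
# and group-cumulated results, over a grid of smoothing parameters and
# correction modes.

#' Run the full co-occurrence analysis
#'
#' Executes the whole pipeline for every combination of smoothing-parameter
#' pair and correction mode: builds the distance and spatial-weight
#' matrices, the occurrence-probability surface, runs the Monte-Carlo
#' ensemble, classifies every taxon pair against its envelope, and (when a
#' hierarchy is supplied) cumulates counts by relatedness category. The
#' default parameter grid is the three (k, d0) pairs (5, 30), (3, 30),
#' (10, 50) crossed with the three correction modes — nine models.
#'
#' @param sites site table (data frame) with site_id and coordinates.
#' @param Y binary presence-absence matrix; its rownames must all appear in
#'   `sites$site_id`.
#' @param taxonomy optional hierarchy data frame; enables relatedness
#'   categories and group cumulation.
#' @param k_d0 list of c(k, d0) pairs.
#' @param offset distance offset, km.
#' @param modes character vector of correction modes.
#' @param n_rounds simulation rounds per model.
#' @param seed master seed; model runs get deterministic derived seeds.
#' @param distance_mode `"haversine"`, `"euclidean"` or `"precomputed"`.
#' @param dist_matrix precomputed km distance matrix (with
#'   `distance_mode = "precomputed"`).
#' @param pool pooling level for [pool_columns()] (`"none"` default).
#' @return object of class `racocos_run`: list with `models` (one result per
#'   model: ensemble, pair results, classification 4-tuple, group results),
#'   `diagnostics`, `OP` per parameter pair, and the resolved `config`.
#' @export
racocos_run <- function(sites, Y, taxonomy = NULL,
                        k_d0 = list(c(5, 30), c(3, 30), c(10, 50)),
                        offset = 0.1,
                        modes = c("uncorrected", "soft", "hard"),
                        n_rounds = 1000L, seed = 1L,
                        distance_mode = c("haversine", "euclidean", "precomputed"),
                        dist_matrix = NULL, pool = "none") {
  distance_mode <- match.arg(distance_mode)
  Y <- validate_presence(Y)
  if (!is.null(rownames(Y))) {
    if (!all(rownames(Y) %in% as.character(sites$site_id)))
      stop("presence matrix contains site ids absent from the site table")
    sites <- sites[match(rownames(Y), as.character(sites$site_id)), , drop = FALSE]
  }
  if (!identical(pool, "none")) {
    if (is.null(taxonomy)) stop("pooling requires a taxonomy")
    Y <- pool_columns(Y, taxonomy, pool)
    taxonomy <- pool_hierarchy(taxonomy, pool)
  }
  dist <- pairwise_distance(sites, distance_mode, dist_matrix = dist_matrix)

  taxa <- colnames(Y)
  categories <- NULL
  if (!is.null(taxonomy)) {
    known <- taxa %in% taxonomy$taxon_id
    if (all(known)) {
      pu <- pair_universe(taxa)
      categories <- pair_relatedness(pu$taxon_a, pu$taxon_b, taxonomy)
    } else {
      warning("taxa missing from hierarchy; group cumulation skipped")
    }
  }

  models <- list()
  OPs <- list()
  model_seed <- 0L
  for (p in k_d0) {
    W <- weight_matrix(dist, k = p[1], d0 = p[2], offset = offset)
    OPs[[paste0("k", p[1], "_d0", p[2])]] <- occurrence_probability(Y, W)
    for (mode in modes) {
      model_seed <- model_seed + 1L
      ens <- simulate_ensemble(Y, W, mode = mode, n_rounds = n_rounds,
                               seed = seed + 7919L * model_seed,
                               params = list(k = p[1], d0 = p[2],
                                             offset = offset))
      pr <- pair_results(Y, ens)
      groups <- if (!is.null(categories))
        cumulate_groups(categories, pr$m, ens) else NULL
      models[[paste0("k", p[1], "_d0", p[2], "_", mode)]] <- list(
        k = p[1], d0 = p[2], mode = mode, ensemble = ens, pairs = pr,
        classification = classification_summary(pr),
        total_observed = sum(pr$m),
        total_simulated_mean = sum(ens$mu_mean),
        groups = groups)
    }
  }

  structure(list(
    models = models, OP = OPs,
    diagnostics = list(richness = taxa_per_site_distribution(Y),
                       taxon_load = mean_cooccurring_taxa(Y)),
    categories = categories,
    config = list(k_d0 = k_d0, offset = offset, modes = modes,
                  n_rounds = n_rounds, seed = seed,
                  distance_mode = distance_mode, pool = pool,
                  n_sites = nrow(Y), n_taxa = ncol(Y), N = sum(Y))
  ), class = "racocos_run")
}

#' @export
print.racocos_run <- function(x, ...) {
  cfg <- x$config
  cat("Range-constrained co-occurrence analysis\n")
  cat("  sites:", cfg$n_sites, " taxa:", cfg$n_taxa, " presences:", cfg$N, "\n")
  cat("  models:", length(x$models), " rounds each:", cfg$n_rounds, "\n")
  for (nm in names(x$models)) {
    cl <- x$models[[nm]]$classification
    cat(sprintf("  %-24s below/within0/within+/above: %d/%d/%d/%d\n",
                nm, cl[1], cl[2], cl[3], cl[4]))
  }
  invisible(x)
}

#' Write a run's artifact bundle
#'
#' Emits per-model pair_results and group_results tables, the OP matrices,
#' richness/taxon-load diagnostics, and a JSON run summary (resolved config,
#' seed, per-model four-way classification tallies and simulated totals).
#'
#' @param run a `racocos_run`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "racocos_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(run$models)) {
    m <- run$models[[nm]]
    p1 <- file.path(dir, paste0("pair_results_", nm, ".tsv"))
    pr <- m$pairs
    if (!is.null(run$categories)) pr$category <- run$categories
    write_table_generic(pr, p1); paths <- c(paths, p1)
    if (!is.null(m$groups)) {
      p2 <- file.path(dir, paste0("group_results_", nm, ".tsv"))
      write_table_generic(m$groups, p2); paths <- c(paths, p2)
    }
  }
  for (nm in names(run$OP)) {
    p <- file.path(dir, paste0("OP_", nm, ".csv"))
    write_matrix_table(run$OP[[nm]], p); paths <- c(paths, p)
  }
  pd <- file.path(dir, "diagnostics.tsv")
  write_table_generic(run$diagnostics$richness$freq, pd)
  pt <- file.path(dir, "taxon_load.tsv")
  write_table_generic(run$diagnostics$taxon_load, pt)
  summary <- list(
    config = run$config,
    models = lapply(run$models, function(m)
      list(k = m$k, d0 = m$d0, mode = m$mode,
           classification = as.list(m$classification),
           total_observed = m$total_observed,
           total_simulated_mean = m$total_simulated_mean)))
  pj <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, pd, pt, pj))
}
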