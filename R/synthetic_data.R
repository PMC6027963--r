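# Synthetic study systems: clustered limestone-like site networks,
# kernel-shaped partially allopatric taxon ranges, uneven sampling effort,
# and optional imposed pairwise exclusion. Everything is reproducible from
# the scenario seed, and the full parameter set travels with the data.

#' Define a synthetic co-occurrence scenario
#'
#' Bundles every parameter of the generator. Defaults mirror the scale and
#' statistical structure of an opportunistically sampled museum dataset of
#' rock-dwelling snails: ~1649 sites clustered in karst-like patches over a
#' Balkan-sized (500 x 500 km) planar extent, a few dozen taxa with
#' Gaussian-kernel ranges of 30-120 km bandwidth (hence partial allopatry),
#' and lognormal per-site sampling-effort multipliers (sigma = 1) that make
#' the taxa-per-site distribution right-skewed.
#'
#' @param n_sites number of sites (default 1649).
#' @param extent_km planar extent, c(width, height) in km.
#' @param clustering fraction of sites placed around cluster parents
#'   (Thomas-type process); 0 = uniform.
#' @param n_clusters number of cluster parents.
#' @param cluster_sd_km Gaussian scatter of clustered sites around their
#'   parent, km.
#' @param n_taxa number of taxa.
#' @param bandwidth_km range of per-taxon Gaussian range-kernel bandwidths,
#'   km (sampled uniformly per taxon).
#' @param prevalence range of per-taxon occurrence probability at the range
#'   centroid under unit effort (sampled uniformly per taxon).
#' @param effort_sigma lognormal sigma of per-site sampling-effort
#'   multipliers (mean fixed at 1); 0 = homogeneous effort.
#' @param detectability per-taxon detection multiplier (scalar or length
#'   n_taxa).
#' @param exclusion_pairs optional 2-column matrix/data frame of taxon index
#'   or id pairs that may never co-occur: wherever both would be present,
#'   one (chosen at random) is removed.
#' @param seed integer seed; the same scenario always generates identical
#'   data.
#' @return object of class `racocos_scenario` (a list of the above).
#' @export
synthetic_scenario <- function(n_sites = 1649, extent_km = c(500, 500),
                               clustering = 0.8, n_clusters = 60,
                               cluster_sd_km = 8,
                               n_taxa = 40, bandwidth_km = c(30, 120),
                               prevalence = c(0.4, 0.9),
                               effort_sigma = 1, detectability = 1,
                               exclusion_pairs = NULL, seed = 1) {
  stopifnot(n_sites >= 2, n_taxa >= 2, all(extent_km > 0),
            clustering >= 0, clustering <= 1, n_clusters >= 1,
            cluster_sd_km >= 0, effort_sigma >= 0)
  if (!is.null(exclusion_pairs)) {
    exclusion_pairs <- as.matrix(exclusion_pairs)
    stopifnot(ncol(exclusion_pairs) == 2)
  }
  structure(list(n_sites = as.integer(n_sites), extent_km = extent_km,
                 clustering = clustering, n_clusters = as.integer(n_clusters),
                 cluster_sd_km = cluster_sd_km, n_taxa = as.integer(n_taxa),
                 bandwidth_km = bandwidth_km, prevalence = prevalence,
                 effort_sigma = effort_sigma, detectability = detectability,
                 exclusion_pairs = exclusion_pairs, seed = as.integer(seed)),
            class = "racocos_scenario")
}

#' Generate a synthetic site table
#'
#' Places sites on the planar extent. With `clustering > 0` a Thomas-type
#' parent-offspring process is used: cluster parents fall uniformly, each
#' clustered site picks a random parent and scatters around it with Gaussian
#' noise (reflected into the extent); the remaining sites are uniform.
#'
#' @param scenario a `racocos_scenario`.
#' @return data frame: site_id, x, y (km).
#' @export
generate_sites <- function(scenario) {
  stopifnot(inherits(scenario, "racocos_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_sites
  ex <- scenario$extent_km
  n_cl <- stats::rbinom(1L, n, scenario$clustering)
  x <- stats::runif(n, 0, ex[1]); y <- stats::runif(n, 0, ex[2])
  if (n_cl > 0L) {
    px <- stats::runif(scenario$n_clusters, 0, ex[1])
    py <- stats::runif(scenario$n_clusters, 0, ex[2])
    parent <- sample.int(scenario$n_clusters, n_cl, replace = TRUE)
    x[seq_len(n_cl)] <- reflect(px[parent] + stats::rnorm(n_cl, 0, scenario$cluster_sd_km), ex[1])
    y[seq_len(n_cl)] <- reflect(py[parent] + stats::rnorm(n_cl, 0, scenario$cluster_sd_km), ex[2])
  }
  data.frame(site_id = sprintf("s%04d", seq_len(n)), x = x, y = y,
             stringsAsFactors = FALSE)
}

# reflect coordinates into [0, hi]
reflect <- function(v, hi) {
  v <- abs(v)
  over <- v > hi
  v[over] <- 2 * hi - v[over]
  pmin(pmax(v, 0), hi)
}

#' Generate a synthetic presence-absence matrix
#'
#' Per-cell presence probability is
#' `prevalence_t * exp(-d_it^2 / (2 * bandwidth_t^2)) * effort_i *
#' detectability_t`, clipped to \[0, 1\], where d_it is the distance from
#' site i to taxon t's range centroid. Effort multipliers are lognormal with
#' mean 1 and sigma `effort_sigma`, emulating uneven sampling activity. For
#' each imposed exclusion pair, one member (picked at random) is removed
#' from every site where both drew present; the pre-exclusion matrix is kept
#' in the truth record.
#'
#' @param scenario a `racocos_scenario`.
#' @param sites site table from [generate_sites()] (regenerated if omitted).
#' @return list: `Y` (binary sites x taxa matrix), `truth` (scenario, taxon
#'   table with centroids/bandwidths/prevalences, per-site effort, and the
#'   pre-exclusion matrix).
#' @export
generate_presence <- function(scenario, sites = generate_sites(scenario)) {
  stopifnot(inherits(scenario, "racocos_scenario"))
  set.seed(scenario$seed + 1L)
  n <- nrow(sites); T_ <- scenario$n_taxa
  ex <- scenario$extent_km
  taxa <- data.frame(
    taxon_id = sprintf("t%03d", seq_len(T_)),
    cx = stats::runif(T_, 0, ex[1]), cy = stats::runif(T_, 0, ex[2]),
    bandwidth = stats::runif(T_, scenario$bandwidth_km[1], scenario$bandwidth_km[2]),
    prevalence = stats::runif(T_, scenario$prevalence[1], scenario$prevalence[2]),
    detectability = rep_len(scenario$detectability, T_),
    stringsAsFactors = FALSE)
  effort <- if (scenario$effort_sigma > 0)
    stats::rlnorm(n, meanlog = -scenario$effort_sigma^2 / 2,
                  sdlog = scenario$effort_sigma) else rep(1, n)

  d2 <- outer(sites$x, taxa$cx, "-")^2 + outer(sites$y, taxa$cy, "-")^2
  kern <- exp(-sweep(d2, 2L, 2 * taxa$bandwidth^2, "/"))
  p <- sweep(kern, 2L, taxa$prevalence * taxa$detectability, "*") * effort
  p <- pmin(p, 1)
  Y0 <- matrix(stats::rbinom(n * T_, 1L, p), n, T_,
               dimnames = list(sites$site_id, taxa$taxon_id))

  Y <- Y0
  if (!is.null(scenario$exclusion_pairs)) {
    ep <- scenario$exclusion_pairs
    for (r in seq_len(nrow(ep))) {
      a <- resolve_taxon(ep[r, 1], taxa$taxon_id)
      b <- resolve_taxon(ep[r, 2], taxa$taxon_id)
      both <- which(Y[, a] == 1L & Y[, b] == 1L)
      if (length(both)) {
        drop_a <- stats::runif(length(both)) < 0.5
        Y[both[drop_a], a] <- 0L
        Y[both[!drop_a], b] <- 0L
      }
    }
  }
  list(Y = Y,
       truth = list(scenario = scenario, taxa = taxa, effort = effort,
                    pre_exclusion = Y0))
}

resolve_taxon <- function(t, ids) {
  if (is.character(t)) {
    i <- match(t, ids)
    if (is.na(i)) stop("unknown taxon in exclusion pair: ", t)
    i
  } else as.integer(t)
}

#' Generate a synthetic taxon hierarchy
#'
#' Assigns the scenario's taxa to a nested hierarchy shaped like a
#' rock-dwelling snail community: one outgroup at the class level, a block
#' of families, a block of congeneric-subfamily genera, and the remainder as
#' morphospecies of a focal genus nested in main clades and subclades. This
#' exercises all seven relatedness categories.
#'
#' @param scenario a `racocos_scenario`.
#' @return hierarchy data frame usable with [pair_relatedness()] and
#'   [pool_columns()].
#' @export
generate_taxonomy <- function(scenario) {
  T_ <- scenario$n_taxa
  ids <- sprintf("t%03d", seq_len(T_))
  n_out <- 1L
  n_fam <- max(1L, round(0.25 * T_))
  n_gen <- max(1L, round(0.2 * T_))
  n_focal <- T_ - n_out - n_fam - n_gen
  if (n_focal < 2L) stop("scenario too small for a focal-genus hierarchy")
  h <- data.frame(taxon_id = ids, class = "Gastropoda",
                  subclass = NA_character_, family = NA_character_,
                  subfamily = NA_character_, genus = NA_character_,
                  main_clade = NA_character_, subclade = NA_character_,
                  species = NA_character_, stringsAsFactors = FALSE)
  i <- 1L
  h$subclass[i] <- "Caenogastropoda"; i <- i + n_out
  fam <- i:(i + n_fam - 1L)
  h$subclass[fam] <- "Pulmonata"
  h$family[fam] <- sprintf("Fam%02d", seq_len(n_fam))
  # one non-alopiine clausiliid so subfamily-level (III) pairs exist
  h$family[fam[n_fam]] <- "Clausiliidae"
  h$subfamily[fam[n_fam]] <- "Baleinae"
  i <- i + n_fam
  gen <- i:(i + n_gen - 1L)
  h$subclass[gen] <- "Pulmonata"; h$family[gen] <- "Clausiliidae"
  h$subfamily[gen] <- "Alopiinae"
  h$genus[gen] <- sprintf("Gen%02d", seq_len(n_gen)); i <- i + n_gen
  foc <- i:T_
  h$subclass[foc] <- "Pulmonata"; h$family[foc] <- "Clausiliidae"
  h$subfamily[foc] <- "Alopiinae"; h$genus[foc] <- "Focalis"
  n_main <- max(2L, ceiling(n_focal / 6))
  main <- rep_len(seq_len(n_main), n_focal)
  h$main_clade[foc] <- sprintf("M%02d", main)
  h$subclade[foc] <- sprintf("M%02d.%d", main,
                             stats::ave(main, main, FUN = function(v)
                               rep_len(1:2, length(v))))
  h$species[foc] <- sprintf("sp%02d", seq_len(n_focal))
  h
}
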