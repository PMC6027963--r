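# Observed/simulated co-occurrence counting, envelope classification,
# rescaling, and group cumulation.

#' Pairwise co-occurrence counts
#'
#' Number of sites where both taxa of each pair are present. A site holding
#' n presences contributes (n^2 - n) / 2 pairwise co-occurrences in total.
#'
#' @param M binary sites-x-taxa matrix.
#' @return symmetric taxa-x-taxa matrix of co-occurrence counts (the
#'   diagonal holds per-taxon presence totals).
#' @export
cooccurrence_counts <- function(M) {
  M <- validate_presence(M)
  C <- crossprod(M)
  storage.mode(C) <- "integer"
  C
}

# Upper-triangle co-occurrence counts in pair_index() order.
pair_cooccurrence_vector <- function(M) {
  C <- crossprod(M)
  as.integer(C[upper.tri(C)])
}

#' Rescaled co-occurrence statistic
#'
#' Linearly rescales an observed pairwise count m against its simulated
#' envelope so that m equal to the simulated minimum, mean and maximum maps
#' to -1, 0 and +1 respectively:
#' \deqn{m' = (m - \bar\mu)/(\bar\mu - \mu_{min}) \quad (m \le \bar\mu),
#'  \qquad m' = (m - \bar\mu)/(\mu_{max} - \bar\mu) \quad (m > \bar\mu)}
#' Values beyond +/-1 mean the observation lies outside the simulated range.
#' When the relevant denominator is zero (a degenerate envelope, common for
#' rare or strongly allopatric pairs) the statistic is undefined and `NA` is
#' returned rather than a silent 0.
#'
#' @param m observed count(s).
#' @param mu_min,mu_mean,mu_max simulated envelope statistics.
#' @return numeric vector; `NA` where undefined.
#' @export
rescale_m <- function(m, mu_min, mu_mean, mu_max) {
  k <- max(length(m), length(mu_min), length(mu_mean), length(mu_max))
  m <- rep_len(m, k); mu_min <- rep_len(mu_min, k)
  mu_mean <- rep_len(mu_mean, k); mu_max <- rep_len(mu_max, k)
  if (any(mu_min > mu_mean | mu_mean > mu_max))
    stop("envelope must satisfy mu_min <= mu_mean <= mu_max")
  lower <- m <= mu_mean
  den <- ifelse(lower, mu_mean - mu_min, mu_max - mu_mean)
  out <- ifelse(den > 0, (m - mu_mean) / den, NA_real_)
  # m exactly at the mean is 0 even if that branch's denominator degenerates
  out[m == mu_mean] <- 0
  out
}

#' Envelope classification of a taxon pair
#'
#' Classifies an observed count against the simulated min-max range
#' (inclusive bounds): `below` when m < mu_min, `above` when m > mu_max,
#' otherwise `within_zero` (m = 0) or `within_nonzero` (m > 0). The
#' within/zero split matters because an observed zero inside an envelope
#' that itself includes zero is unassessable pairwise.
#'
#' @param m observed count(s).
#' @param mu_min,mu_max simulated envelope bounds.
#' @return character vector with levels below / within_zero /
#'   within_nonzero / above.
#' @export
classify_pair <- function(m, mu_min, mu_max) {
  if (any(mu_min > mu_max)) stop("mu_min must not exceed mu_max")
  ifelse(m < mu_min, "below",
         ifelse(m > mu_max, "above",
                ifelse(m == 0, "within_zero", "within_nonzero")))
}

#' Pairwise results table
#'
#' Joins observed pairwise co-occurrence counts with an ensemble's
#' envelopes, classifies each pair and attaches the rescaled statistic.
#'
#' @param Y the observed binary presence-absence matrix the ensemble was
#'   built from.
#' @param ensemble a `racocos_ensemble` from [simulate_ensemble()].
#' @return data frame: taxon_a, taxon_b, m, mu_min, mu_mean, mu_max,
#'   m_prime, class.
#' @export
pair_results <- function(Y, ensemble) {
  stopifnot(inherits(ensemble, "racocos_ensemble"))
  Y <- validate_presence(Y)
  m <- pair_cooccurrence_vector(Y)
  if (length(m) != nrow(ensemble$pairs))
    stop("presence matrix and ensemble disagree on the number of taxon pairs")
  out <- ensemble$pairs
  out$m <- m
  out$mu_min <- ensemble$mu_min
  out$mu_mean <- ensemble$mu_mean
  out$mu_max <- ensemble$mu_max
  out$m_prime <- rescale_m(m, out$mu_min, out$mu_mean, out$mu_max)
  out$class <- classify_pair(m, out$mu_min, out$mu_max)
  out
}

#' Four-way classification tally
#'
#' Counts of pairs classified below / within (observed zero) / within
#' (observed non-zero) / above the simulated envelopes.
#'
#' @param pairs data frame from [pair_results()].
#' @return named integer vector of length 4.
#' @export
classification_summary <- function(pairs) {
  lv <- c("below", "within_zero", "within_nonzero", "above")
  out <- table(factor(pairs$class, levels = lv))
  stats::setNames(as.integer(out), lv)
}

#' Group-cumulated co-occurrence counts
#'
#' Sums observed pairwise counts within relatedness groups and compares them
#' to the ensemble of per-round group sums: the simulated pairwise counts
#' are summed within each group after every simulation round, and min, mean
#' and max are taken over those per-round sums (never over per-pair
#' envelopes — summing per-pair minima/maxima would understate/overstate
#' the group envelope). This overcomes pairwise-unassessable zeros for rare
#' or allopatric taxa.
#'
#' @param categories vector (one element per pair, in the ensemble's pair
#'   order) of group labels; `NA` = uncategorized, excluded.
#' @param observed integer vector of observed pairwise counts in the same
#'   order.
#' @param ensemble a `racocos_ensemble` (its per-round count matrix is used).
#' @return data frame: category, n_pairs, observed_sum, sim_min, sim_mean,
#'   sim_max.
#' @export
cumulate_groups <- function(categories, observed, ensemble) {
  stopifnot(inherits(ensemble, "racocos_ensemble"))
  if (length(categories) != nrow(ensemble$pairs) ||
      length(observed) != nrow(ensemble$pairs))
    stop("'categories' and 'observed' must have one element per taxon pair")
  keep <- !is.na(categories)
  cats <- unique(categories[keep])
  res <- lapply(cats, function(g) {
    idx <- which(keep & categories == g)
    per_round <- colSums(ensemble$rounds[idx, , drop = FALSE])
    data.frame(category = g, n_pairs = length(idx),
               observed_sum = sum(observed[idx]),
               sim_min = min(per_round), sim_mean = mean(per_round),
               sim_max = max(per_round), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
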