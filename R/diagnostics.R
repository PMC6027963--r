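# Data-quality diagnostics: sampling-effort bias shows up as a right-skewed
# taxa-per-site distribution and as large spread in per-taxon co-occurrence
# load; both guide the choice of correction mode.

#' Taxa-per-site richness distribution
#'
#' Exact frequency table of per-site richness (row sums) with sample
#' moments. Under similar habitats and even sampling effort the distribution
#' should be roughly symmetric around its mean; strong right skew (mode well
#' below the mean) indicates uneven effort.
#'
#' @param M binary sites-x-taxa matrix.
#' @param label source label stored on the result (e.g. "observed").
#' @return object of class `racocos_richness`: list with `freq` (data frame
#'   richness/n_sites), `n_sites`, `mean`, `skewness`, `kurtosis` (excess,
#'   both bias-uncorrected, e1071 type 1), `label`.
#' @export
taxa_per_site_distribution <- function(M, label = "observed") {
  M <- validate_presence(M)
  n <- rowSums(M)
  tab <- table(factor(n, levels = 0:max(n)))
  structure(list(
    freq = data.frame(richness = as.integer(names(tab)),
                      n_sites = as.integer(tab)),
    n_sites = nrow(M),
    mean = mean(n),
    skewness = if (stats::sd(n) > 0) e1071::skewness(n, type = 1) else NA_real_,
    kurtosis = if (stats::sd(n) > 0) e1071::kurtosis(n, type = 1) else NA_real_,
    label = label
  ), class = "racocos_richness")
}

#' @export
print.racocos_richness <- function(x, ...) {
  cat("Taxa-per-site distribution (", x$label, "): ", x$n_sites,
      " sites, mean ", round(x$mean, 2), ", skewness ",
      round(x$skewness, 2), ", excess kurtosis ", round(x$kurtosis, 2),
      "\n", sep = "")
  invisible(x)
}

#' Per-taxon co-occurrence load
#'
#' For each taxon, the mean number of other taxa found at its presence sites
#' (mean over presence sites of site richness minus one). In an unbiased
#' dataset these values vary little across taxa; effort-demanding taxa being
#' recorded mostly at well-explored, rich sites inflates theirs. The
#' alternative bookkeeping — number of distinct partner taxa — is returned
#' alongside.
#'
#' @param Y binary presence-absence matrix.
#' @return data frame: taxon_id, n_presences, mean_cooccurring (NA for
#'   taxa without presences), n_partner_taxa.
#' @export
mean_cooccurring_taxa <- function(Y) {
  Y <- validate_presence(Y)
  rich <- rowSums(Y)
  C <- crossprod(Y)
  taxa <- colnames(Y)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(Y)))
  pres <- diag(C)
  mean_co <- vapply(seq_len(ncol(Y)), function(t) {
    s <- Y[, t] == 1
    if (!any(s)) return(NA_real_)
    mean(rich[s] - 1)
  }, numeric(1))
  partners <- colSums(C > 0) - as.integer(pres > 0)
  data.frame(taxon_id = taxa, n_presences = as.integer(pres),
             mean_cooccurring = mean_co,
             n_partner_taxa = as.integer(partners),
             stringsAsFactors = FALSE)
}

#' Sampling-bias report
#'
#' Puts the observed richness distribution side by side with distributions
#' from simulated (typically uncorrected-null) matrices and flags the data
#' as biased when the observed skewness exceeds every simulated one — the
#' quick assessment that motivates the hard/soft corrections.
#'
#' @param observed `racocos_richness` of the real data.
#' @param simulated list of `racocos_richness` objects from simulated
#'   matrices (matching site counts).
#' @return list: `table` (long data frame of frequencies per source),
#'   `moments` (per source mean/skewness/kurtosis plus deltas vs observed),
#'   `biased` (logical flag).
#' @export
bias_report <- function(observed, simulated) {
  stopifnot(inherits(observed, "racocos_richness"))
  if (inherits(simulated, "racocos_richness")) simulated <- list(simulated)
  for (s in simulated) {
    stopifnot(inherits(s, "racocos_richness"))
    if (s$n_sites != observed$n_sites)
      stop("site counts differ between observed and simulated distributions")
  }
  all_d <- c(list(observed), simulated)
  tab <- do.call(rbind, lapply(all_d, function(d)
    cbind(d$freq, source = d$label, stringsAsFactors = FALSE)))
  mom <- do.call(rbind, lapply(all_d, function(d)
    data.frame(source = d$label, mean = d$mean, skewness = d$skewness,
               kurtosis = d$kurtosis,
               d_mean = d$mean - observed$mean,
               d_skewness = d$skewness - observed$skewness,
               d_kurtosis = d$kurtosis - observed$kurtosis,
               stringsAsFactors = FALSE)))
  sim_skew <- vapply(simulated, function(d) d$skewness, numeric(1))
  list(table = tab, moments = mom,
       biased = length(sim_skew) > 0 && all(observed$skewness > sim_skew))
}
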