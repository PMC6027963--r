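# Taxon hierarchy handling: relatedness categories for stratified
# co-occurrence reporting, and hierarchy-driven column pooling.

#' Ordered taxonomic ranks used by the hierarchy table
#' @export
RANKS <- c("class", "subclass", "family", "subfamily", "genus",
           "main_clade", "subclade", "species")

# Default mapping: rank at which a pair's paths first diverge -> relatedness
# category. A pair diverging at the subclass is related at the class level
# (category I: e.g. a caenogastropod vs a pulmonate), one diverging at the
# family is related at the subclass (II: different pulmonate families), and
# so on down to pairs of morphospecies within one subclade (VII).
default_category_map <- function() {
  data.frame(
    divergence_rank = c("subclass", "family", "subfamily", "genus",
                        "main_clade", "subclade", "species"),
    category = c("I", "II", "III", "IV", "V", "VI", "VII"),
    stringsAsFactors = FALSE
  )
}

validate_hierarchy <- function(hierarchy) {
  stopifnot(is.data.frame(hierarchy))
  if (!"taxon_id" %in% names(hierarchy))
    stop("hierarchy needs a 'taxon_id' column")
  if (anyDuplicated(hierarchy$taxon_id))
    stop("duplicate taxon ids in hierarchy")
  missing_ranks <- setdiff(RANKS, names(hierarchy))
  for (r in missing_ranks) hierarchy[[r]] <- NA_character_
  for (r in RANKS) {
    v <- as.character(hierarchy[[r]])
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    hierarchy[[r]] <- v
  }
  hierarchy
}

#' Relatedness category of a taxon pair
#'
#' Walks the shared, ordered rank path of two taxa and finds the first rank
#' at which both have a value and the values differ (ranks unresolved for
#' either taxon are skipped). That divergence rank is mapped to an ordinal
#' relatedness category (default I-VII, deepest = most closely related).
#' Pairs whose divergence rank has no entry in the map — or that never
#' diverge — are uncategorized (`NA`).
#'
#' @param a,b taxon ids (vectors of equal length are accepted).
#' @param hierarchy data frame with `taxon_id` plus rank columns (any of
#'   class, subclass, family, subfamily, genus, main_clade, subclade,
#'   species); empty strings count as unresolved.
#' @param category_map data frame with columns `divergence_rank`,
#'   `category`; defaults to the seven-category map described above.
#' @return character vector of category labels, `NA` when uncategorized.
#' @export
pair_relatedness <- function(a, b, hierarchy,
                             category_map = default_category_map()) {
  hierarchy <- validate_hierarchy(hierarchy)
  ids <- hierarchy$taxon_id
  ia <- match(as.character(a), ids)
  ib <- match(as.character(b), ids)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown taxon id(s): ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  rank_tbl <- as.matrix(hierarchy[RANKS])
  vapply(seq_along(ia), function(p) {
    pa <- rank_tbl[ia[p], ]
    pb <- rank_tbl[ib[p], ]
    both <- !is.na(pa) & !is.na(pb)
    div <- which(both & pa != pb)
    if (!length(div)) return(NA_character_)
    rank <- RANKS[div[1L]]
    hit <- match(rank, category_map$divergence_rank)
    if (is.na(hit)) NA_character_ else category_map$category[hit]
  }, character(1L))
}

#' All unordered taxon pairs
#'
#' The pair universe of T taxa: exactly T(T-1)/2 unordered pairs, no
#' self-pairs, in the same order as the ensemble's pair table.
#'
#' @param taxa character vector of unique taxon ids (>= 2).
#' @return data frame with columns taxon_a, taxon_b.
#' @export
pair_universe <- function(taxa) {
  pair_index(as.character(taxa))
}

#' Pool a hierarchy to match pooled presence-matrix columns
#'
#' Companion of [pool_columns()]: collapses the hierarchy rows of taxa that
#' share a value at `level` into one row named by that value, keeping the
#' ranks above `level` (identical among members in a consistent hierarchy)
#' and blanking the ranks below. Rows unresolved at `level` pass through.
#'
#' @inheritParams pool_columns
#' @return pooled hierarchy data frame.
#' @export
pool_hierarchy <- function(hierarchy, level) {
  if (identical(level, "none")) return(validate_hierarchy(hierarchy))
  if (!level %in% RANKS) stop("'level' must be one of: none, ",
                              paste(RANKS, collapse = ", "))
  hierarchy <- validate_hierarchy(hierarchy)
  val <- hierarchy[[level]]
  keep <- hierarchy[is.na(val), , drop = FALSE]
  below <- RANKS[seq_along(RANKS) > match(level, RANKS)]
  pooled <- do.call(rbind, lapply(unique(val[!is.na(val)]), function(g) {
    row <- hierarchy[which(val == g)[1L], , drop = FALSE]
    row$taxon_id <- g
    row[below] <- NA_character_
    row
  }))
  out <- rbind(keep, pooled)
  rownames(out) <- NULL
  out
}

#' Pool presence-matrix columns by a hierarchy rank
#'
#' Merges (logical OR) columns whose taxa share the same value at the given
#' rank; columns whose taxon is unresolved at that rank pass through
#' unchanged. This lets one raw matrix plus one hierarchy generate analyses
#' at several taxonomic resolutions (e.g. genus-, clade- or species-level
#' pooling of a focal genus).
#'
#' @param Y binary presence-absence matrix with taxon ids as colnames.
#' @param hierarchy taxon hierarchy data frame (see [pair_relatedness()]).
#' @param level a rank name, or `"none"` for a no-op.
#' @return pooled binary matrix; pooled columns are named by the rank value.
#' @export
pool_columns <- function(Y, hierarchy, level = "none") {
  Y <- validate_presence(Y)
  if (identical(level, "none")) return(Y)
  if (!level %in% RANKS) stop("'level' must be one of: none, ",
                              paste(RANKS, collapse = ", "))
  hierarchy <- validate_hierarchy(hierarchy)
  taxa <- colnames(Y)
  if (is.null(taxa)) stop("presence matrix needs taxon ids as colnames")
  idx <- match(taxa, hierarchy$taxon_id)
  if (anyNA(idx)) stop("taxa absent from hierarchy: ",
                       paste(taxa[is.na(idx)], collapse = ", "))
  val <- hierarchy[[level]][idx]
  keep <- Y[, is.na(val), drop = FALSE]
  groups <- unique(val[!is.na(val)])
  pooled <- vapply(groups, function(g) {
    as.integer(rowSums(Y[, which(!is.na(val) & val == g), drop = FALSE]) > 0)
  }, integer(nrow(Y)))
  if (length(groups)) {
    pooled <- matrix(pooled, nrow = nrow(Y),
                     dimnames = list(rownames(Y), groups))
    cbind(keep, pooled)
  } else keep
}
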