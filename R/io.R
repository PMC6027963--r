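# Flat-file readers and writers. All tables are UTF-8 CSV/TSV with a
# header; the delimiter is auto-detected (tab if the header contains one,
# comma otherwise).

sniff_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", quote = "\"")
}

#' Read a site table
#'
#' Expects columns `site_id, lon, lat` (geographic) or `site_id, x, y`
#' (planar km) and an optional `habitat` column.
#'
#' @param path CSV/TSV file path.
#' @param mode coordinate mode used for validation; `"euclidean"` expects
#'   x/y.
#' @return validated data frame.
#' @export
read_sites <- function(path, mode = c("haversine", "euclidean")) {
  mode <- match.arg(mode)
  validate_sites(read_delim_auto(path), mode)
}

#' Read a presence-absence matrix
#'
#' First column is `site_id`; remaining columns are taxa with 0/1 cells.
#'
#' @param path CSV/TSV file path.
#' @return binary matrix, sites x taxa, with dimnames.
#' @export
read_presence_matrix <- function(path) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) stop("presence matrix needs site_id plus taxon columns")
  Y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Y) <- as.character(df[[1L]])
  storage.mode(Y) <- "numeric"
  validate_presence(Y)
}

#' Write a presence/OP-style matrix
#'
#' Writes a sites-x-taxa matrix in the same layout the readers expect
#' (site_id first column).
#'
#' @param M matrix with site ids as rownames.
#' @param path output file; `.tsv` extension selects tabs.
#' @export
write_matrix_table <- function(M, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(site_id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a taxon hierarchy table
#'
#' Expects `taxon_id` plus any subset of the rank columns in [RANKS]; empty
#' cells mean the rank is unresolved for that taxon.
#'
#' @param path CSV/TSV file path.
#' @return validated hierarchy data frame.
#' @export
read_taxonomy <- function(path) {
  validate_hierarchy(read_delim_auto(path))
}

#' Read a precomputed distance matrix
#'
#' Square CSV/TSV, km units, site ids as header row and first column.
#'
#' @param path file path.
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read_delim_auto(path)
  d <- as.matrix(df[, -1L, drop = FALSE])
  rownames(d) <- as.character(df[[1L]])
  storage.mode(d) <- "numeric"
  pairwise_distance(NULL, mode = "precomputed", dist_matrix = d)
}

write_table_generic <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
}
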