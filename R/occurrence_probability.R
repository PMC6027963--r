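# Occurrence-probability surfaces and the selection-weight matrices that
# constrain the null simulations.

#' Occurrence probability matrix
#'
#' For each taxon t and site i, the occurrence probability is the
#' spatially-weighted fraction of presence sites:
#' \deqn{OP_{it} = \frac{\sum_j W_{ij} Y_{jt}}{\sum_j W_{ij}}}
#' i.e. the sum of spatial weights of the sites where t is present, divided
#' by the sum of weights of all sites. This is a smoothed, probabilistic
#' range definition: OP is high wherever a taxon has many nearby presences.
#'
#' @param Y binary presence-absence matrix, sites x taxa, with site ids as
#'   rownames and taxon ids as colnames.
#' @param W spatial weight matrix from [weight_matrix()]; site labels must
#'   match `Y`'s rownames.
#' @return matrix of the same shape and labels as `Y`, values in \[0, 1\].
#' @export
occurrence_probability <- function(Y, W) {
  Y <- validate_presence(Y)
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || nrow(W) != nrow(Y))
    stop("weight matrix dimensions do not match presence matrix sites")
  if (!is.null(rownames(W)) && !is.null(rownames(Y)) &&
      !identical(rownames(W), rownames(Y)))
    stop("site labels of Y and W do not match")
  denom <- rowSums(W)
  if (any(denom <= 0)) stop("a site has non-positive total weight")
  OP <- (W %*% Y) / denom
  dimnames(OP) <- dimnames(Y)
  OP
}

validate_presence <- function(Y) {
  Y <- as.matrix(Y)
  if (!is.numeric(Y)) stop("presence matrix must be numeric 0/1")
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad)) {
    ij <- arrayInd(bad[seq_len(min(5L, length(bad)))], dim(Y))
    stop("presence matrix has non-binary cells, e.g. at (row,col): ",
         paste(apply(ij, 1, paste, collapse = ","), collapse = "; "))
  }
  if (!is.null(rownames(Y)) && anyDuplicated(rownames(Y)))
    stop("duplicate site ids")
  if (!is.null(colnames(Y)) && anyDuplicated(colnames(Y)))
    stop("duplicate taxon ids")
  Y
}

#' Uncorrected selection weights
#'
#' Rescales the occurrence-probability matrix so its total equals the number
#' of presence records `N`, leaving every element proportional to the raw
#' OP. These are the per-cell selection weights of the uncorrected null
#' model.
#'
#' @param OP occurrence probability matrix from [occurrence_probability()].
#' @param N target total number of presences (the sum of the observed Y).
#' @return selection-weight matrix with attributes `mode = "uncorrected"`
#'   and `total = N`.
#' @export
rescale_uncorrected <- function(OP, N) {
  s <- sum(OP)
  if (s <= 0) stop("OP matrix sums to zero: no presences")
  out <- OP * (N / s)
  structure(out, mode = "uncorrected", total = N)
}

#' Randomized per-site richness vector
#'
#' Builds the correction vector of the hard and soft null models: the
#' observed per-site richness vector n (row sums of Y) in uniformly
#' randomized order (hard), optionally with 1 added to every element so that
#' no site is ever fully excluded (soft). A fresh permutation must be drawn
#' for every simulation round.
#'
#' @param Y binary presence-absence matrix.
#' @param mode `"hard"` or `"soft"`.
#' @return integer vector of length `nrow(Y)`.
#' @export
correction_vector <- function(Y, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  n <- rowSums(validate_presence(Y))
  nprime <- sample(n)     # uniform (Fisher-Yates) permutation
  if (mode == "soft") nprime <- nprime + 1
  unname(nprime)
}

#' Richness-corrected selection weights
#'
#' Multiplies each row of the occurrence-probability matrix by the permuted
#' richness vector and rescales the product so its total equals `N`. Sites
#' assigned a zero element (possible under the hard correction only) get an
#' all-zero row and are effectively excluded from that simulation round.
#'
#' @param OP occurrence probability matrix.
#' @param nprime permuted richness vector from [correction_vector()].
#' @param N target total number of presences.
#' @param mode label stored on the result (`"hard"` or `"soft"`).
#' @return selection-weight matrix summing to `N`.
#' @export
corrected_selection_weights <- function(OP, nprime, N, mode = "hard") {
  if (length(nprime) != nrow(OP))
    stop("correction vector length must equal the number of sites")
  if (any(nprime < 0)) stop("correction vector must be non-negative")
  M <- OP * nprime       # column-recycled: scales row i by nprime[i]
  s <- sum(M)
  if (s <= 0) stop("corrected weight matrix sums to zero")
  structure(M * (N / s), mode = mode, total = N)
}
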