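# Small fixtures built in code, shared across test files.

# 4 sites x 3 taxa with known structure, used against brute-force oracles
fixture_Y43 <- function() {
  matrix(c(1, 1, 0,
           1, 0, 1,
           0, 1, 1,
           1, 1, 1),
         nrow = 4, byrow = TRUE,
         dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
}

# planar site table with pairwise distances controlled by x only
fixture_sites_line <- function(xs) {
  data.frame(site_id = paste0("s", seq_along(xs)), x = xs, y = 0,
             stringsAsFactors = FALSE)
}

# Brute-force Eq. 2: OP_it = sum_j W_ij Y_jt / sum_j W_ij, explicit loops
oracle_op <- function(Y, W) {
  OP <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  for (i in seq_len(nrow(Y))) for (t in seq_len(ncol(Y))) {
    num <- 0; den <- 0
    for (j in seq_len(nrow(Y))) {
      num <- num + W[i, j] * Y[j, t]
      den <- den + W[i, j]
    }
    OP[i, t] <- num / den
  }
  OP
}

# Brute-force pairwise co-occurrence counts, exhaustive over sites and pairs
oracle_cooc <- function(M) {
  T_ <- ncol(M)
  out <- matrix(0L, T_, T_, dimnames = list(colnames(M), colnames(M)))
  for (a in seq_len(T_)) for (b in seq_len(T_)) {
    cnt <- 0L
    for (i in seq_len(nrow(M))) if (M[i, a] == 1 && M[i, b] == 1) cnt <- cnt + 1L
    out[a, b] <- cnt
  }
  out
}

# Minimal hand-built ensemble object for functions that consume one
fake_ensemble <- function(rounds, taxa) {
  pairs <- racocos::pair_universe(taxa)
  stopifnot(nrow(rounds) == nrow(pairs))
  structure(list(pairs = pairs,
                 mu_min = apply(rounds, 1, min),
                 mu_mean = rowMeans(rounds),
                 mu_max = apply(rounds, 1, max),
                 rounds = rounds, mode = "uncorrected",
                 n_rounds = ncol(rounds), seed = NULL,
                 N = NA, params = NULL),
            class = "racocos_ensemble")
}
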