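test_that("simulate_presence places exactly N ones on positive-weight cells", {
  w <- matrix(c(2, 0, 1, 0, 3, 4), 2, 3)
  # exactly N positive cells -> deterministic selection of all of them
  psi <- simulate_presence(w, 4)
  expect_equal(which(psi == 1L), which(w > 0))
  # N = 0 -> all-zero
  expect_equal(sum(simulate_presence(w, 0)), 0)
  # zero-weight cells never selected, totals conserved, across random draws
  set.seed(5)
  for (rep in 1:50) {
    psi <- simulate_presence(w, 3)
    expect_equal(sum(psi), 3)
    expect_true(all(psi[w == 0] == 0))
  }
  expect_error(simulate_presence(w, 5), "fewer")
})

test_that("per-draw selection law is proportional to weights", {
  # 4 cells, weights 0.7/0.1/0.1/0.1, N = 1: empirical selection frequency
  # must match the exact multinomial law within 3-sigma binomial bounds
  w <- matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4)
  n_draws <- 20000
  set.seed(11)
  hits <- integer(4)
  for (i in seq_len(n_draws)) {
    sel <- which(simulate_presence(w, 1) == 1L)
    hits[sel] <- hits[sel] + 1L
  }
  p <- c(0.7, 0.1, 0.1, 0.1)
  freq <- hits / n_draws
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n_draws)))
})

test_that("sampler agrees in distribution with base R weighted sampling", {
  # independent oracle: sample(prob=, replace=FALSE) has the same sequential
  # per-draw law; compare full inclusion frequencies for N = 2 of 4
  w <- c(0.5, 0.25, 0.15, 0.1)
  n_draws <- 8000
  set.seed(21)
  ours <- integer(4); ref <- integer(4)
  wm <- matrix(w, 1, 4)
  for (i in seq_len(n_draws)) {
    s1 <- which(simulate_presence(wm, 2) == 1L)
    ours[s1] <- ours[s1] + 1L
    s2 <- sample.int(4, 2, replace = FALSE, prob = w)
    ref[s2] <- ref[s2] + 1L
  }
  # inclusion probabilities: compare the two empirical vectors within joint
  # 3-sigma bounds of their difference
  p1 <- ours / n_draws; p2 <- ref / n_draws
  se <- sqrt(p2 * (1 - p2) * 2 / n_draws)
  expect_true(all(abs(p1 - p2) <= 3 * se))
})

test_that("ensembles conserve presences, are seed-reproducible, and degenerate correctly", {
  sc <- synthetic_scenario(n_sites = 30, n_taxa = 6, seed = 2)
  s <- generate_sites(sc); Y <- generate_presence(sc, s)$Y
  W <- weight_matrix(pairwise_distance(s, "euclidean"), 5, 30)
  for (mode in c("uncorrected", "soft", "hard")) {
    e1 <- simulate_ensemble(Y, W, mode, n_rounds = 10, seed = 42)
    e2 <- simulate_ensemble(Y, W, mode, n_rounds = 10, seed = 42)
    expect_identical(e1$rounds, e2$rounds)
    expect_true(all(e1$mu_min <= e1$mu_mean & e1$mu_mean <= e1$mu_max))
  }
  one <- simulate_ensemble(Y, W, "hard", n_rounds = 1, seed = 3)
  expect_equal(one$mu_min, one$mu_mean)
  expect_equal(one$mu_mean, one$mu_max)
})

test_that("disjoint far-apart ranges never co-occur under the uncorrected null", {
  # two tight clusters 500 km apart; taxon A only in the west, B only east:
  # cross-range OP' is numerically zero, so mu_max for the (A, B) pair is 0
  s <- fixture_sites_line(c(0, 1, 2, 500, 501, 502))
  Y <- cbind(A = c(1, 1, 1, 0, 0, 0), B = c(0, 0, 0, 1, 1, 1))
  rownames(Y) <- s$site_id
  W <- weight_matrix(pairwise_distance(s, "euclidean"), 5, 30)
  ens <- simulate_ensemble(Y, W, "uncorrected", n_rounds = 50, seed = 8)
  expect_equal(ens$mu_max[1], 0)
})

test_that("hard correction tracks the observed richness distribution", {
  # right-skewed sampling effort: hard-corrected simulations must match the
  # observed taxa-per-site distribution far more closely (total variation
  # distance) than uncorrected ones, and match mean richness
  sc <- synthetic_scenario(n_sites = 150, n_taxa = 15, effort_sigma = 1.2,
                           seed = 4)
  s <- generate_sites(sc); Y <- generate_presence(sc, s)$Y
  W <- weight_matrix(pairwise_distance(s, "euclidean"), 3, 30)
  OP <- occurrence_probability(Y, W)
  N <- sum(Y)
  obs <- rowSums(Y)
  tv <- function(a, b) {
    lv <- 0:max(a, b)
    sum(abs(tabulate(factor(a, lv), length(lv)) -
            tabulate(factor(b, lv), length(lv)))) / (2 * length(a))
  }
  set.seed(10)
  tv_hard <- tv_unc <- numeric(20)
  mean_hard <- numeric(20)
  w_unc <- rescale_uncorrected(OP, N)
  for (r in 1:20) {
    wh <- corrected_selection_weights(OP, correction_vector(Y, "hard"), N)
    rh <- rowSums(simulate_presence(wh, N))
    ru <- rowSums(simulate_presence(w_unc, N))
    tv_hard[r] <- tv(rh, obs); tv_unc[r] <- tv(ru, obs)
    mean_hard[r] <- mean(rh)
  }
  expect_lt(mean(tv_hard), mean(tv_unc))
  expect_equal(mean(mean_hard), mean(obs), tolerance = 1e-9)  # N conserved
})
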