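test_that("pair universe has T(T-1)/2 order-normalized pairs", {
  expect_equal(nrow(pair_universe(sprintf("t%02d", 1:47))), 1081)
  expect_equal(nrow(pair_universe(sprintf("t%02d", 1:61))), 1830)
  expect_equal(nrow(pair_universe(sprintf("t%02d", 1:73))), 2628)
  pu <- pair_universe(c("a", "b"))
  expect_equal(pu, data.frame(taxon_a = "a", taxon_b = "b"))
  expect_false(any(pu$taxon_a == pu$taxon_b))
  expect_error(pair_universe(c("a", "a")), "duplicate")
  expect_error(pair_universe("a"))
})

make_hierarchy <- function() {
  data.frame(
    taxon_id  = c("caeno", "famA", "famB", "cla_other", "genA", "genB",
                  "m_sub1a", "m_sub1b", "m_sub2a", "sp1", "sp2"),
    class     = "Gastropoda",
    subclass  = c("Caenogastropoda", rep("Pulmonata", 10)),
    family    = c(NA, "FamA", "FamB", rep("Clausiliidae", 8)),
    subfamily = c(NA, NA, NA, "Baleinae", rep("Alopiinae", 7)),
    genus     = c(NA, NA, NA, NA, "GenA", "GenB", rep("Focalis", 5)),
    main_clade = c(rep(NA, 6), "M1", "M1", "M2", "M1", "M1"),
    subclade  = c(rep(NA, 6), "M1.a", "M1.b", "M2.a", "M1.a", "M1.a"),
    species   = c(rep(NA, 9), "sp1", "sp2"),
    stringsAsFactors = FALSE)
}

test_that("relatedness categories follow the divergence rank", {
  h <- make_hierarchy()
  expect_equal(pair_relatedness("caeno", "famA", h), "I")    # class level
  expect_equal(pair_relatedness("famA", "famB", h), "II")    # subclass level
  expect_equal(pair_relatedness("cla_other", "genA", h), "III") # family level
  expect_equal(pair_relatedness("genA", "genB", h), "IV")    # subfamily level
  expect_equal(pair_relatedness("m_sub1a", "m_sub2a", h), "V")  # diff main clades
  expect_equal(pair_relatedness("m_sub1a", "m_sub1b", h), "VI") # same main clade
  expect_equal(pair_relatedness("sp1", "sp2", h), "VII")     # morphospecies
  # symmetry and vectorization
  expect_equal(pair_relatedness("famA", "caeno", h), "I")
  pu <- pair_universe(h$taxon_id)
  cats <- pair_relatedness(pu$taxon_a, pu$taxon_b, h)
  cats_rev <- pair_relatedness(pu$taxon_b, pu$taxon_a, h)
  expect_identical(cats, cats_rev)
  expect_equal(length(cats), nrow(pu))
  # identical paths (no divergence) are uncategorized
  h2 <- rbind(h, h[11, ]); h2$taxon_id[12] <- "sp2bis"
  expect_true(is.na(pair_relatedness("sp2", "sp2bis", h2)))
  expect_error(pair_relatedness("nope", "sp1", h), "unknown")
})

test_that("synthetic taxonomy covers all seven categories", {
  sc <- synthetic_scenario(n_sites = 10, n_taxa = 40, seed = 1)
  h <- generate_taxonomy(sc)
  expect_equal(nrow(h), 40)
  pu <- pair_universe(h$taxon_id)
  cats <- pair_relatedness(pu$taxon_a, pu$taxon_b, h)
  expect_true(all(c("I", "II", "III", "IV", "V", "VI", "VII") %in% cats))
  expect_equal(sum(!is.na(cats)) + sum(is.na(cats)), nrow(pu))
})

test_that("column pooling ORs member columns and leaves others alone", {
  h <- make_hierarchy()
  Y <- matrix(0L, 3, 4,
              dimnames = list(paste0("s", 1:3),
                              c("sp1", "sp2", "genA", "famA")))
  Y["s1", "sp1"] <- 1L; Y["s2", "sp2"] <- 1L
  Y["s1", "genA"] <- 1L; Y["s3", "famA"] <- 1L
  pooled <- pool_columns(Y, h, "genus")
  expect_true("Focalis" %in% colnames(pooled))
  expect_equal(unname(pooled[, "Focalis"]), c(1L, 1L, 0L))   # OR of sp1, sp2
  expect_equal(pooled[, "famA"], Y[, "famA"])                # unresolved rank
  expect_equal(ncol(pooled), 3)   # sp1+sp2 -> Focalis; genA -> GenA kept
  # identical columns pool to one identical column
  Y2 <- cbind(sp1 = c(1L, 0L, 1L), sp2 = c(1L, 0L, 1L))
  rownames(Y2) <- paste0("s", 1:3)
  p2 <- pool_columns(Y2, h, "genus")
  expect_equal(unname(p2[, "Focalis"]), c(1L, 0L, 1L))
  # no-op and bad level
  expect_identical(pool_columns(Y, h, "none"), racocos:::validate_presence(Y))
  expect_error(pool_columns(Y, h, "order"))
})

test_that("hierarchy pooling collapses rows consistently with column pooling", {
  h <- make_hierarchy()
  hp <- pool_hierarchy(h, "genus")
  expect_true("Focalis" %in% hp$taxon_id)
  foc <- hp[hp$taxon_id == "Focalis", ]
  expect_equal(foc$subfamily, "Alopiinae")       # ranks above survive
  expect_true(is.na(foc$species))                # ranks below blanked
  expect_true(all(c("caeno", "famA") %in% hp$taxon_id))  # unresolved kept
  # pooled matrix columns all resolve against the pooled hierarchy
  Y <- matrix(0L, 2, 3, dimnames = list(c("s1", "s2"),
                                        c("sp1", "genA", "famA")))
  pc <- pool_columns(Y, h, "genus")
  expect_true(all(colnames(pc) %in% hp$taxon_id))
})
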