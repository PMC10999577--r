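test_that("Shannon index matches hand-computed values", {
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon_index(c(7)), 0)
  expect_equal(shannon_index(c(1, 1, 2)), 1.5 * log(2), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Simpson dominance matches hand-computed values", {
  expect_equal(simpson_index(c(9)), 1)
  expect_equal(simpson_index(c(2, 2, 2, 2)), 0.25)
  expect_equal(simpson_index(c(1, 1, 2)), 0.375)
})

test_that("Chao1 uses the bias-corrected singleton/doubleton form", {
  expect_equal(chao1_index(c(5, 7, 9)), 3)  # no singletons
  # S_obs 5, F1 2, F2 1: 5 + 2*1/(2*2)
  expect_equal(chao1_index(c(1, 1, 2, 5, 9)), 5.5)
  expect_equal(chao1_index(c(1, 1, 2, 5, 9), bias_corrected = FALSE),
               5 + 4 / 2)
  set.seed(3)
  for (i in 1:20) {
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    expect_gte(chao1_index(x), sum(x > 0))
  }
})

test_that("ACE matches the hand-computed classic estimator", {
  expect_equal(ace_index(c(20, 30, 40)), 3)  # no rare class correction
  # counts (1,1,2,3,12,15): S_abund 2, S_rare 4, N_rare 7, F1 2,
  # C = 5/7, gamma^2 = max(5.6 * 8/42 - 1, 0): ACE = 2 + 5.6 + 2.8*gamma^2
  expect_equal(ace_index(c(1, 1, 2, 3, 12, 15)), 7.786666666667,
               tolerance = 1e-10)
  expect_warning(v <- ace_index(c(1, 1, 20)), "singleton")
  set.seed(4)
  for (i in 1:20) {
    x <- rpois(40, 3) + rbinom(40, 1, 0.3)
    x <- x[x > 0]
    if (length(x) == 0 || all(x == 1)) next
    expect_gte(suppressWarnings(ace_index(x)), sum(x > 0) - 1e-10)
  }
})

test_that("indices agree with the independent vegan implementations", {
  set.seed(5)
  for (i in 1:10) {
    x <- rpois(50, 1.5)
    x[sample(50, 10)] <- rpois(10, 40)
    if (sum(x) == 0) next
    est <- vegan::estimateR(x)
    expect_equal(chao1_index(x), unname(est["S.chao1"]), tolerance = 1e-8)
    expect_equal(suppressWarnings(ace_index(x)), unname(est["S.ACE"]),
                 tolerance = 1e-8)
    expect_equal(shannon_index(x), unname(vegan::diversity(x)),
                 tolerance = 1e-10)
    expect_equal(1 - simpson_index(x),
                 unname(vegan::diversity(x, "simpson")), tolerance = 1e-10)
  }
})

test_that("indices ignore OTU order and zero-count padding", {
  x <- c(4, 1, 1, 9, 2)
  perm <- sample(x)
  expect_equal(shannon_index(perm), shannon_index(x))
  expect_equal(simpson_index(c(x, 0, 0)), simpson_index(x))
  expect_equal(chao1_index(c(x, 0, 0, 0)), chao1_index(x))
})

test_that("taxon aggregation yields unit row sums and exact shares", {
  counts <- matrix(c(30, 70, 50, 50), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("o1", "o2")))
  tax <- data.frame(otu_id = c("o1", "o2"),
                    phylum = c("Proteobacteria", "Firmicutes"),
                    genus = c("Geobacter", "Bacillus"))
  ra <- aggregate_taxa(counts, tax, "phylum")
  expect_equal(ra["s1", "Proteobacteria"], 0.3)
  expect_equal(ra["s1", "Firmicutes"], 0.7)
  expect_equal(unname(rowSums(ra)), c(1, 1), tolerance = 1e-12)
  # a single phylum aggregates to 1
  tax$phylum <- "Proteobacteria"
  expect_equal(unname(aggregate_taxa(counts, tax, "phylum")[, 1]), c(1, 1))
})

test_that("generated OTU table aggregates to the configured profiles", {
  ds <- nf_dataset()
  cnt <- otu_counts(ds$otu)
  tax <- ds$otu[, c("otu_id", "kingdom", "phylum", "genus")]
  ra <- aggregate_taxa(cnt, tax, "phylum")
  expect_equal(unname(rowSums(ra)), rep(1, nrow(ra)), tolerance = 1e-12)
  # multinomial means: the SWI-100 surface profile targets 25.47%
  expect_equal(otu_profile("SWI", 1, "0-30")[["Proteobacteria"]], 0.2547)
  got <- mean(ra[grep("^SWI-100\\|0-30", rownames(ra)), "Proteobacteria"])
  expect_equal(got, 0.2547, tolerance = 0.05)
})
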