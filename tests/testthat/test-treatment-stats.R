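test_that("one-way ANOVA matches a hand-worked decomposition", {
  # groups (1,2,3), (2,3,4), (6,7,8): SSB = 42, SSW = 6, F = 21
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- one_way_anova(v, g)
  expect_equal(an$f_stat, 21)
  expect_equal(an$mse, 1)
  expect_equal(an$df_error, 6)
  expect_equal(an$p_value, 0.001953125, tolerance = 1e-7)
})

test_that("degenerate and separated groups follow the conventions", {
  an <- one_way_anova(c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(an$f_stat, 0)
  expect_equal(an$p_value, 1)
  an <- one_way_anova(c(0, 0, 1e-9, 10, 10, 10 + 1e-9),
                      c("a", "a", "a", "b", "b", "b"))
  expect_lt(an$p_value, 1e-6)
  expect_error(one_way_anova(1:3, c("a", "a", "a")), "2 groups")
  expect_error(one_way_anova(1:3, c("a", "b", "b")), "n >= 2")
})

test_that("letter display spans identical and well-separated groups", {
  v <- rep(5, 9); g <- rep(c("x", "y", "z"), each = 3)
  expect_equal(unname(lsd_letters(v, g)), c("a", "a", "a"))
  v <- c(10, 10.1, 9.9, 5, 5.1, 4.9, 1, 1.1, 0.9)
  g <- rep(c("hi", "mid", "lo"), each = 3)
  let <- lsd_letters(v, g)
  expect_equal(unname(let[c("hi", "mid", "lo")]), c("a", "b", "c"))
})

test_that("extreme grain-yield treatments receive different letters", {
  # means +/- sd with n = 3, realized as {m - s, m, m + s}
  mk <- function(m, s) c(m - s, m, m + s)
  v <- c(mk(6.21, 0.94), mk(15.37, 2.77), mk(42.91, 5.84), mk(75.61, 7.18))
  g <- rep(c("TI-0", "TI-40", "TI-70", "TI-100"), each = 3)
  let <- lsd_letters(v, g)
  expect_true(length(intersect(strsplit(let[["TI-0"]], "")[[1]],
                               strsplit(let[["TI-100"]], "")[[1]])) == 0)
  # the top-yield group carries "a"
  expect_match(let[["TI-100"]], "a")
})

test_that("letters agree with brute-force pairwise LSD on random fixtures", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    n <- sample(3:5, 1)
    mu <- rnorm(k, 0, sample(c(0.5, 1, 3), 1))
    v <- rnorm(k * n, rep(mu, each = n), 1)
    g <- rep(paste0("g", seq_len(k)), each = n)
    sig <- brute_force_lsd(v, g)
    let <- lsd_letters(v, g)
    expect_true(letters_consistent(let[rownames(sig)], sig))
    # and the package's own pairwise matrix matches the oracle
    expect_equal(unclass(lsd_pairwise(v, g))[seq_len(k), seq_len(k)], sig)
  }
})

test_that("protected LSD gates on the omnibus test", {
  set.seed(7)
  v <- rnorm(12); g <- rep(letters[1:4], each = 3)
  an <- one_way_anova(v, g)
  if (an$p_value >= 0.05) {
    expect_true(all(!lsd_pairwise(v, g, protected = TRUE)))
  }
})

test_that("mean/sd summaries use the sample convention", {
  s <- summarize_mean_sd(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$sd, 1)
  s <- summarize_mean_sd(5)
  expect_equal(s$sd, 0); expect_equal(s$flag, "single_observation")
  expect_equal(summarize_mean_sd(c(4, 4, 4))$sd, 0)
})

test_that("treatment comparison emits mean/sd/letter rows per variable", {
  ds <- generate_experiment(noisy_config(0.05), seed = 9,
                            tables = "plant")
  tc <- treatment_comparison(ds$plant, c("grain_yield", "n_pct"))
  expect_setequal(unique(tc$variable), c("grain_yield", "n_pct"))
  expect_equal(nrow(tc), 16)
  expect_true(all(tc$n == 3))
  expect_true(all(nchar(tc$letters) >= 1))
})
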