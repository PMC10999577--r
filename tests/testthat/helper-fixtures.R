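# Shared fixtures: the noise-free reference experiment is deterministic and
# used by many files, so generate it once per test run.
.fixture_env <- new.env()

nf_dataset <- function() {
  if (is.null(.fixture_env$ds)) {
    .fixture_env$ds <- generate_experiment(generator_config(), seed = 0)
  }
  .fixture_env$ds
}

nf_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    ds <- nf_dataset()
    cfg <- nfate_config()
    .fixture_env$pipe <- list(
      leaching = leaching_summary(ds$leachate, cfg),
      fate = fate_partitions(ds, cfg))
  }
  .fixture_env$pipe
}

# a noisy generator configuration for stochastic tests
noisy_config <- function(sigma = 0.1) {
  generator_config(sigma = list(volume = sigma, conc = sigma, atom = sigma,
                                plant = sigma, soil = sigma, ct = 0))
}

# brute-force pairwise LSD oracle: pooled-MSE t test per pair, computed
# from first principles (no package internals)
brute_force_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  lv <- levels(groups)
  k <- length(lv)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  ss_w <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  df_e <- length(values) - k
  mse <- ss_w / df_e
  tcrit <- qt(1 - alpha / 2, df_e)
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    lsd <- tcrit * sqrt(mse * (1 / n[i] + 1 / n[j]))
    sig[i, j] <- sig[j, i] <- abs(m[i] - m[j]) > lsd
  }
  sig
}

# letters consistent with a significance matrix: share a letter iff the
# pair is NOT significantly different
letters_consistent <- function(lets, sig) {
  k <- length(lets)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    shared <- length(intersect(strsplit(lets[i], "")[[1]],
                               strsplit(lets[j], "")[[1]])) > 0
    if (shared == sig[i, j]) return(FALSE)
  }
  TRUE
}
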