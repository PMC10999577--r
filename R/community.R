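#' Shannon diversity of one sample
#'
#' H = -sum p_i ln p_i over OTUs with positive counts (natural log; some
#' ecosystems report log2 — this package does not).
#'
#' @param counts non-negative integer vector of OTU counts.
#' @return Shannon index.
#' @export
shannon_index <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all-zero sample", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Simpson index of one sample
#'
#' Dominance form D = sum p_i^2. The complement 1 - D (Gini-Simpson) is
#' also reported by [alpha_diversity()]; published verbal comparisons do
#' not always disambiguate the two.
#'
#' @param counts non-negative integer vector of OTU counts.
#' @return Simpson dominance D.
#' @export
simpson_index <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("all-zero sample", call. = FALSE)
  p <- counts[counts > 0] / total
  sum(p^2)
}

#' Chao1 richness estimator
#'
#' Bias-corrected form by default: S_obs + F1 (F1 - 1) / (2 (F2 + 1)),
#' with F1/F2 the singleton/doubleton counts; `bias_corrected = FALSE`
#' gives the classic F1^2 / (2 F2) form (undefined when F2 = 0).
#'
#' @param counts non-negative integer vector of OTU counts.
#' @param bias_corrected use the bias-corrected form (default TRUE).
#' @return estimated richness, always >= observed richness.
#' @export
chao1_index <- function(counts, bias_corrected = TRUE) {
  stopifnot(all(counts >= 0))
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    if (f2 == 0 && f1 > 0) {
      warning("classic Chao1 undefined with no doubletons; using bias-corrected")
      return(chao1_index(counts, bias_corrected = TRUE))
    }
    s_obs + if (f1 > 0) f1^2 / (2 * f2) else 0
  }
}

#' ACE richness estimator
#'
#' Classic abundance-based coverage estimator with rare threshold 10:
#' S_ACE = S_abund + S_rare / C_ace + F1 gamma^2 / C_ace, where
#' C_ace = 1 - F1 / N_rare is the sample coverage of the rare class and
#' gamma^2 the rare-class coefficient of variation (floored at 0). When
#' the rare class is all singletons (C_ace = 0) the estimator is undefined
#' and Chao1 is returned with a warning.
#'
#' @param counts non-negative integer vector of OTU counts.
#' @param rare_threshold abundance cutoff for the rare class.
#' @return estimated richness.
#' @export
ace_index <- function(counts, rare_threshold = 10) {
  stopifnot(all(counts >= 0))
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("ACE undefined (rare class is all singletons); falling back to Chao1")
    return(chao1_index(c(counts)))
  }
  fi <- tabulate(rare, nbins = rare_threshold)
  gamma2 <- max(
    s_rare / c_ace * sum(seq_len(rare_threshold) *
                           (seq_len(rare_threshold) - 1) * fi) /
      (n_rare * (n_rare - 1)) - 1,
    0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Alpha diversity table for an OTU count matrix
#'
#' @param counts integer matrix, samples in rows, OTUs in columns.
#' @param rarefy_to optional depth to subsample every sample to before
#'   computing indices (no rarefaction by default); requires a seed for
#'   reproducibility.
#' @param seed RNG seed used only when `rarefy_to` is given.
#' @return data.frame: sample_id, observed, chao1, ace, shannon,
#'   simpson (dominance D) and inv_simpson_complement (1 - D).
#' @export
alpha_diversity <- function(counts, rarefy_to = NULL, seed = 1) {
  counts <- as.matrix(counts)
  if (!is.null(rarefy_to)) {
    set.seed(seed)
    counts <- t(apply(counts, 1, function(x) {
      if (sum(x) <= rarefy_to) return(x)
      drawn <- sample(rep.int(seq_along(x), x), rarefy_to)
      tabulate(drawn, nbins = length(x))
    }))
  }
  data.frame(
    sample_id = if (is.null(rownames(counts))) seq_len(nrow(counts))
                else rownames(counts),
    observed = apply(counts, 1, function(x) sum(x > 0)),
    chao1 = apply(counts, 1, chao1_index),
    ace = apply(counts, 1, ace_index),
    shannon = apply(counts, 1, shannon_index),
    simpson = apply(counts, 1, simpson_index),
    simpson_complement = 1 - apply(counts, 1, simpson_index),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate OTU counts to a taxonomic rank as relative abundances
#'
#' Sums counts per lineage at the requested rank within each sample and
#' divides by the sample total, so rows sum to 1.
#'
#' @param counts integer matrix, samples x OTUs (column names = OTU ids).
#' @param taxonomy data.frame with `otu_id` and rank columns
#'   (`phylum`, `genus`).
#' @param rank `"phylum"` or `"genus"`.
#' @return matrix samples x taxa of relative abundances.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  lin <- taxonomy[[rank]][match(colnames(counts), taxonomy$otu_id)]
  lin[is.na(lin) | lin == ""] <- "unclassified"
  agg <- t(rowsum(t(counts), group = lin))
  sweep(agg, 1, rowSums(agg), "/")
}
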