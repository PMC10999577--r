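#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 copy number over the dilution
#' series (ten-fold steps spanning 1e9 down to 1e3 in the reference assay
#' design). Amplification efficiency is 10^(-1/slope) - 1; perfect doubling
#' chemistry gives slope -3.3219 and efficiency 1. Assays with efficiency
#' outside [0.7, 1.2] or r-squared below 0.98 are flagged with a warning,
#' not rejected.
#'
#' @param log10_copies numeric vector of log10 template copies.
#' @param ct matching Ct values.
#' @param gene assay label.
#' @return object of class `standard_curve`: gene, slope, intercept,
#'   efficiency, r_squared.
#' @export
fit_standard_curve <- function(log10_copies, ct, gene = "") {
  stopifnot(length(log10_copies) == length(ct))
  if (length(unique(log10_copies)) < 3) {
    stop("standard curve needs at least 3 distinct dilution levels",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-8) {
    stop("degenerate standard curve: zero slope", call. = FALSE)
  }
  # direct r-squared (summary.lm warns on the noise-free perfect fit)
  sst <- sum((ct - mean(ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  eff <- 10^(-1 / slope) - 1
  if (slope >= 0) warning(sprintf("%s: positive slope %.3f", gene, slope))
  if (eff < 0.7 || eff > 1.2) {
    warning(sprintf("%s: efficiency %.3f outside [0.7, 1.2]", gene, eff))
  }
  if (is.finite(r2) && r2 < 0.98) {
    warning(sprintf("%s: r-squared %.4f below 0.98", gene, r2))
  }
  structure(list(gene = gene, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = eff, r_squared = r2),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve [%s]\n", x$gene))
  cat(sprintf("  slope %.4f  intercept %.3f  efficiency %.1f%%  r2 %.5f\n",
              x$slope, x$intercept, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Average a Ct triplicate with a one-well outlier rule
#'
#' Drops at most one well whose distance from the triplicate median exceeds
#' `max_dev` cycles, then averages the rest.
#'
#' @param ct numeric vector of replicate Ct values.
#' @param max_dev outlier threshold, cycles.
#' @return mean Ct after the outlier rule.
#' @export
average_ct <- function(ct, max_dev = 0.5) {
  ct <- ct[is.finite(ct)]
  if (length(ct) == 0) return(NA_real_)
  if (length(ct) >= 3) {
    dev <- abs(ct - stats::median(ct))
    worst <- which.max(dev)
    if (dev[worst] > max_dev) ct <- ct[-worst]
  }
  mean(ct)
}

#' Convert Ct to copy number via a standard curve
#'
#' copies = 10^((ct - intercept) / slope). Ct at or beyond the non-detect
#' guard (default cycle 40, or within 3 cycles of the no-template control)
#' is reported as 0 copies with a flag.
#'
#' @param ct Ct value (already triplicate-averaged; see [average_ct()]).
#' @param curve a [fit_standard_curve()] result.
#' @param ntc_ct no-template-control Ct (NA if none run).
#' @param max_ct absolute non-detect guard, cycles.
#' @return copy number; attribute "nondetect" TRUE when guarded to 0.
#' @export
quantify_copies <- function(ct, curve, ntc_ct = NA_real_, max_ct = 40) {
  guard <- max_ct
  if (is.finite(ntc_ct)) guard <- min(guard, ntc_ct - 3)
  nondetect <- !is.finite(ct) | ct >= guard
  copies <- ifelse(nondetect, 0, 10^((ct - curve$intercept) / curve$slope))
  attr(copies, "nondetect") <- nondetect
  copies
}

# the four assay pairings: functional gene over its matching 16S reference
.gene_pairings <- c(amoA_bacteria = "16S_bacteria",
                    amoA_archaea = "16S_archaea",
                    nirS = "16S_bacteria",
                    nosZ = "16S_bacteria")

#' Relative abundance of a functional gene
#'
#' Functional gene copies divided by the matching 16S reference copies:
#' bacterial amoA, nirS and nosZ against bacterial 16S; archaeal amoA
#' against archaeal 16S. Reaction-volume rescaling cancels.
#'
#' @param functional_copies copy number of the functional gene.
#' @param reference_16s_copies copy number of the matching 16S assay.
#' @return unitless ratio; NA when the reference is 0.
#' @export
relative_abundance <- function(functional_copies, reference_16s_copies) {
  ifelse(reference_16s_copies > 0,
         functional_copies / reference_16s_copies, NA_real_)
}

#' Quantify a qPCR plate table end-to-end
#'
#' Fits one standard curve per gene from the `is_standard` wells, averages
#' sample triplicates with the outlier rule, converts to copy numbers with
#' the NTC guard, and attaches the relative abundance of each functional
#' gene against its 16S reference within the same sample.
#'
#' @param qpcr qPCR table: sample_id, gene, well, ct, is_standard,
#'   log10_copies (NA for sample wells). NTC wells have sample_id "NTC".
#' @return list with `curves` (per-gene [fit_standard_curve()] objects) and
#'   `abundance` (sample_id x gene: copies, relative_abundance, flag).
#' @export
qpcr_abundance <- function(qpcr) {
  genes <- unique(qpcr$gene)
  curves <- lapply(genes, function(g) {
    std <- qpcr[qpcr$gene == g & qpcr$is_standard, ]
    if (nrow(std) == 0) return(NULL)
    fit_standard_curve(std$log10_copies, std$ct, gene = g)
  })
  names(curves) <- genes
  samp <- qpcr[!qpcr$is_standard & qpcr$sample_id != "NTC", ]
  rows <- list()
  for (g in intersect(genes, unique(samp$gene))) {
    if (is.null(curves[[g]])) next
    ntc <- qpcr$ct[qpcr$gene == g & qpcr$sample_id == "NTC"]
    ntc_ct <- if (length(ntc)) min(ntc, na.rm = TRUE) else NA_real_
    sg <- samp[samp$gene == g, ]
    for (sid in unique(sg$sample_id)) {
      ct_bar <- average_ct(sg$ct[sg$sample_id == sid])
      cp <- quantify_copies(ct_bar, curves[[g]], ntc_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene = g, copies = as.numeric(cp),
        flag = if (isTRUE(attr(cp, "nondetect"))) "nondetect" else "",
        stringsAsFactors = FALSE)
    }
  }
  ab <- do.call(rbind, rows)
  ab$relative_abundance <- NA_real_
  for (g in names(.gene_pairings)) {
    ref_g <- .gene_pairings[[g]]
    idx <- which(ab$gene == g)
    for (i in idx) {
      ref <- ab$copies[ab$gene == ref_g & ab$sample_id == ab$sample_id[i]]
      if (length(ref) == 1) {
        ab$relative_abundance[i] <- relative_abundance(ab$copies[i], ref)
      }
    }
  }
  list(curves = curves, abundance = ab)
}
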