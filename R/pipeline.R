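#' Write a dataset to a directory of CSV files
#'
#' Writes leachate.csv, soil.csv, plant.csv, qpcr.csv and otu.csv (wide
#' counts + taxonomy) plus truth.json when ground truth is attached.
#' UTF-8, "." decimal separator; numeric round-trip is exact to R's full
#' write precision (15 significant digits).
#'
#' @param dataset an `nfate_dataset` (or plain list of tables).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (tab in intersect(c("leachate", "soil", "plant", "qpcr", "otu"),
                        names(dataset))) {
    p <- file.path(dir, paste0(tab, ".csv"))
    utils::write.csv(dataset[[tab]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$truth)) {
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(as.data.frame(unclass(dataset$truth)), p,
                         digits = NA, na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a dataset from a directory of CSV files
#'
#' Inverse of [write_dataset()]; qPCR and OTU tables are optional.
#'
#' @param dir directory holding leachate.csv, soil.csv, plant.csv and
#'   optionally qpcr.csv, otu.csv, truth.json.
#' @return list of class `nfate_dataset`.
#' @export
read_dataset <- function(dir) {
  need <- c("leachate", "soil", "plant")
  dataset <- list()
  for (tab in c(need, "qpcr", "otu")) {
    p <- file.path(dir, paste0(tab, ".csv"))
    if (file.exists(p)) {
      dataset[[tab]] <- utils::read.csv(p, stringsAsFactors = FALSE,
                                        check.names = FALSE)
    } else if (tab %in% need) {
      stop(sprintf("required input file missing: %s", p), call. = FALSE)
    }
  }
  p <- file.path(dir, "truth.json")
  if (file.exists(p)) dataset$truth <- jsonlite::fromJSON(p)
  class(dataset) <- "nfate_dataset"
  dataset
}

#' Compare irrigation modes at matched N rates
#'
#' For each nonzero N fraction present under both modes: the NUE gain of
#' SWI over TI (delta_nue = NUE_SWI - NUE_TI) and the leaching-loss-rate
#' reduction (delta_nll = NLL_TI - NLL_SWI), plus their ranges.
#'
#' @param fate treatment-level fate table (from [fate_partitions()]).
#' @param leach treatment-level leaching table (from [leaching_summary()]).
#' @param design treatment design.
#' @return list with `by_rate` (per n_fraction deltas) and `range`
#'   (min/max of each delta).
#' @export
compare_irrigation_modes <- function(fate, leach, design = treatment_design()) {
  d <- merge(design, fate, by = "treatment_id")
  l <- leach[, c("treatment_id", "loss_rate_pct")]
  d <- merge(d, l, by = "treatment_id")
  rows <- list()
  for (fr in sort(unique(d$n_fraction[d$n_fraction > 0]))) {
    ti <- d[d$irrigation_mode == "TI" & d$n_fraction == fr, ]
    sw <- d[d$irrigation_mode == "SWI" & d$n_fraction == fr, ]
    if (nrow(ti) != 1 || nrow(sw) != 1) {
      warning(sprintf("unmatched treatment pair at n_fraction %.2f", fr))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_fraction = fr, delta_nue = sw$plant_pct - ti$plant_pct,
      delta_nll = ti$loss_rate_pct - sw$loss_rate_pct,
      stringsAsFactors = FALSE)
  }
  by_rate <- do.call(rbind, rows)
  list(by_rate = by_rate,
       range = data.frame(
         quantity = c("delta_nue", "delta_nll"),
         min = c(min(by_rate$delta_nue), min(by_rate$delta_nll)),
         max = c(max(by_rate$delta_nue), max(by_rate$delta_nll))))
}

.round_df <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Run the full accounting pipeline on a dataset directory
#'
#' validation -> leaching accounting -> isotope fate -> qPCR gene
#' abundance -> community metrics -> treatment statistics, writing
#' leaching_summary.csv, fate_partition.csv, gene_abundance.csv,
#' diversity.csv, stats_summary.csv and report.md to `out_dir`, plus a
#' run manifest (input digests, stages, warnings). qPCR and OTU stages
#' are skipped with a warning when their inputs are absent. Any
#' validation violation aborts the run and removes partial outputs.
#'
#' @param input_dir directory of input CSVs (see [read_dataset()]).
#' @param out_dir output directory.
#' @param config an [nfate_config()].
#' @return the run manifest (list), invisibly; outputs on disk.
#' @export
run_pipeline <- function(input_dir, out_dir, config = nfate_config()) {
  dataset <- read_dataset(input_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  warnings_log <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(.round_df(df), p, row.names = FALSE)
    written <<- c(written, p)
  }

  viol <- validate_dataset(dataset, config)
  if (nrow(viol) > 0) {
    file.remove(written[file.exists(written)])
    stop(sprintf("validation failed with %d violation(s); first: [%s row %s] %s",
                 nrow(viol), viol$table[1], viol$row[1], viol$message[1]),
         call. = FALSE)
  }

  stages <- c("validate")
  ls <- leaching_summary(dataset$leachate, config)
  emit(ls$per_device, "leaching_summary.csv")
  neg <- ls$treatment$treatment_id[ls$treatment$flag != ""]
  if (length(neg)) warnings_log <- c(warnings_log,
    sprintf("negative blank-corrected loss rate: %s", paste(neg, collapse = ", ")))
  stages <- c(stages, "leaching")

  fp <- fate_partitions(dataset, config)
  emit(fp$treatment, "fate_partition.csv")
  stages <- c(stages, "isotope_fate")

  if (!is.null(dataset$qpcr)) {
    qa <- qpcr_abundance(dataset$qpcr)
    nd <- qa$abundance$sample_id[qa$abundance$flag == "nondetect"]
    if (length(nd)) warnings_log <- c(warnings_log,
      sprintf("qPCR non-detects: %s", paste(unique(nd), collapse = ", ")))
    emit(qa$abundance, "gene_abundance.csv")
    stages <- c(stages, "qpcr")
  } else {
    warnings_log <- c(warnings_log, "qpcr.csv absent: qPCR stage skipped")
  }

  if (!is.null(dataset$otu)) {
    cnt <- otu_counts(dataset$otu)
    emit(alpha_diversity(cnt), "diversity.csv")
    tax <- dataset$otu[, c("otu_id", "kingdom", "phylum", "genus")]
    for (rank in c("phylum", "genus")) {
      ra <- aggregate_taxa(cnt, tax, rank)
      emit(data.frame(sample_id = rownames(ra), ra, check.names = FALSE),
           sprintf("taxa_%s.csv", rank))
    }
    stages <- c(stages, "community")
  } else {
    warnings_log <- c(warnings_log, "otu.csv absent: community stage skipped")
  }

  stats_tab <- treatment_comparison(dataset$plant, alpha = config$alpha)
  fate_stats <- treatment_comparison(fp$per_replicate, alpha = config$alpha)
  emit(rbind(stats_tab, fate_stats), "stats_summary.csv")
  stages <- c(stages, "statistics")

  cmp <- compare_irrigation_modes(fp$treatment, ls$treatment, config$design)

  report <- c(
    "# Nitrogen fate accounting report", "",
    "## Leaching (treatment level, exit port)", "",
    knit_table(.round_df(ls$treatment[, c("treatment_id", "total_volume",
      "annualized_volume", "n_mass", "annualized_n_loss", "loss_rate_pct")], 4)),
    "", "## Labeled-N fate partition (% of applied 15N)", "",
    knit_table(.round_df(fp$treatment, 4)),
    "", "## SWI vs TI at matched N rates", "",
    knit_table(.round_df(cmp$by_rate, 4)), "",
    if (length(warnings_log)) c("## Warnings", "", paste("-", warnings_log))
    else "No warnings.")
  writeLines(unlist(report), file.path(out_dir, "report.md"))
  written <- c(written, file.path(out_dir, "report.md"))

  manifest <- list(
    inputs = as.list(tools::md5sum(list.files(input_dir, full.names = TRUE))),
    stages = stages, outputs = written, warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# minimal markdown table renderer (no extra dependency)
knit_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, body)
}
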