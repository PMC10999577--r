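#' Default treatment design for the two-irrigation by four-N-rate experiment
#'
#' Eight treatments: two irrigation modes (TI, traditional flooding refilled
#' to 8 cm when below 5 cm; SWI, shallow wet irrigation held at 1-2 cm)
#' crossed with four nitrogen rates expressed as fractions (0, 0.4, 0.7, 1.0)
#' of the full recommended rate of 148 kg N ha-1. Phosphorus (67 kg ha-1) and
#' potassium (114 kg ha-1) are applied uniformly to all fertilized
#' treatments; the zero-N controls receive no fertilizer at all.
#'
#' @param full_n_rate Full nitrogen rate in kg ha-1.
#' @param p_rate,k_rate P and K rates (kg ha-1) for fertilized treatments.
#' @return A data.frame with columns `treatment_id`, `irrigation_mode`,
#'   `n_fraction`, `n_rate`, `p_rate`, `k_rate`.
#' @export
#' @examples
#' treatment_design()
treatment_design <- function(full_n_rate = 148, p_rate = 67, k_rate = 114) {
  modes <- c("TI", "SWI")
  fracs <- c(0, 0.4, 0.7, 1.0)
  grid <- expand.grid(n_fraction = fracs, irrigation_mode = modes,
                      stringsAsFactors = FALSE)
  grid$n_rate <- round(grid$n_fraction * full_n_rate)
  grid$treatment_id <- paste0(grid$irrigation_mode, "-", round(grid$n_fraction * 100))
  grid$p_rate <- ifelse(grid$n_fraction > 0, p_rate, 0)
  grid$k_rate <- ifelse(grid$n_fraction > 0, k_rate, 0)
  grid[, c("treatment_id", "irrigation_mode", "n_fraction",
           "n_rate", "p_rate", "k_rate")]
}

#' Device geometry and annualization constants
#'
#' Describes one soil-column lysimeter device and the scaling constants used
#' to annualize per-device totals to a hectare-year basis: `season_fraction`
#' (R_t, growing season as a fraction of the year) and `devices_per_hectare`
#' (R_s, the number of device footprints per hectare, 10000 / surface_area).
#'
#' The actual column dimensions are not published with the study design this
#' package models; the defaults (0.071 m2 surface, R_t = 0.35) are documented
#' stand-ins used consistently by the synthetic generator, so that forward
#' accounting and generation invert each other exactly.
#'
#' @param surface_area Soil column surface area, m2.
#' @param season_fraction R_t, fraction of the year occupied by the season.
#' @return An object of class `device_geometry` (a list).
#' @export
device_geometry <- function(surface_area = 0.071, season_fraction = 0.35) {
  stopifnot(surface_area > 0, season_fraction > 0, season_fraction <= 1)
  structure(list(
    surface_area = surface_area,
    season_fraction = season_fraction,
    devices_per_hectare = 10000 / surface_area
  ), class = "device_geometry")
}

#' Isotope-dilution constants
#'
#' `fertilizer_abundance` is the atom% 15N of the labeled urea (c in the
#' dilution equation); `natural_abundance` is the natural soil background
#' (d, 0.368 atom%). The control abundance b is taken from the matched
#' zero-N treatment (same irrigation mode, same compartment/period/layer),
#' falling back to `natural_abundance` when no control is available.
#'
#' @param fertilizer_abundance atom% 15N of the labeled fertilizer.
#' @param natural_abundance natural background atom% 15N.
#' @return A list of class `isotope_constants`.
#' @export
isotope_constants <- function(fertilizer_abundance = 10.0,
                              natural_abundance = 0.368) {
  stopifnot(fertilizer_abundance > natural_abundance)
  structure(list(fertilizer_abundance = fertilizer_abundance,
                 natural_abundance = natural_abundance),
            class = "isotope_constants")
}

#' Convert an areal N rate to a per-device mass
#'
#' kg ha-1 equals 0.1 g m-2, so a device of `surface_area` m2 receives
#' rate * surface_area / 10 grams.
#'
#' @param rate_kg_ha rate in kg ha-1.
#' @param geom a [device_geometry()].
#' @return grams per device.
#' @export
kg_ha_to_g_device <- function(rate_kg_ha, geom) {
  rate_kg_ha * geom$surface_area / 10
}

#' Inverse of [kg_ha_to_g_device()]
#' @param mass_g grams per device.
#' @param geom a [device_geometry()].
#' @return kg ha-1.
#' @export
g_device_to_kg_ha <- function(mass_g, geom) {
  mass_g * 10 / geom$surface_area
}

#' Split-application fertilization schedule
#'
#' Labeled urea is applied in three pulses: basal before transplanting,
#' tiller fertilizer at the tillering stage and panicle (spike) fertilizer at
#' the spike stage. Default split 40/30/30 of the treatment's seasonal N.
#'
#' @param total_n_g total labeled N for the treatment, g per device.
#' @param days day-of-season of the three applications.
#' @param split fractions for basal/tiller/panicle, summing to 1.
#' @param atom_pct_15n atom% 15N of the applied urea.
#' @return data.frame with columns stage, day, n_mass, atom_pct_15n.
#' @export
fertilization_schedule <- function(total_n_g,
                                   days = c(basal = 0, tiller = 25, panicle = 60),
                                   split = c(0.4, 0.3, 0.3),
                                   atom_pct_15n = 10.0) {
  stopifnot(length(days) == 3, length(split) == 3,
            abs(sum(split) - 1) < 1e-12, !is.unsorted(days))
  data.frame(stage = c("basal", "tiller", "panicle"),
             day = as.integer(days),
             n_mass = total_n_g * split,
             atom_pct_15n = atom_pct_15n,
             stringsAsFactors = FALSE)
}

#' Full pipeline configuration
#'
#' Bundles the treatment design, device geometry, isotope constants and the
#' switches that resolve genuinely ambiguous accounting choices:
#' \describe{
#'   \item{annualize_mode}{`"upscale"` (default): annualization multiplies by
#'     devices-per-hectare and divides by the season fraction;
#'     `"area_fraction"` is the alternative orientation for sensitivity
#'     checks only.}
#'   \item{loss_port}{depth port treated as the column's exit flux for loss
#'     accounting; default `"lower"` (30-60 cm) — water passing 60 cm has
#'     left the system, and summing both ports would double-count.}
#' }
#'
#' @param design treatment design data.frame, see [treatment_design()].
#' @param geometry a [device_geometry()].
#' @param isotope an [isotope_constants()].
#' @param annualize_mode annualization orientation, see Details.
#' @param loss_port `"lower"` or `"upper"`.
#' @param alpha significance level for treatment statistics.
#' @return list of class `nfate_config`.
#' @export
nfate_config <- function(design = treatment_design(),
                         geometry = device_geometry(),
                         isotope = isotope_constants(),
                         annualize_mode = c("upscale", "area_fraction"),
                         loss_port = c("lower", "upper"),
                         alpha = 0.05) {
  structure(list(design = design, geometry = geometry, isotope = isotope,
                 annualize_mode = match.arg(annualize_mode),
                 loss_port = match.arg(loss_port),
                 alpha = alpha),
            class = "nfate_config")
}

# required columns per record family; validation is schema-first
.nfate_schemas <- list(
  leachate = c("treatment_id", "replicate", "day", "depth_port", "volume",
               "tn", "nh4", "no3", "atom_pct_15n"),
  soil = c("treatment_id", "replicate", "period", "layer", "tn_pct", "nh4",
           "no3", "alkali_n", "atom_pct_15n", "dry_mass"),
  plant = c("treatment_id", "replicate", "dry_weight", "n_pct",
            "atom_pct_15n", "plant_height", "grain_yield", "straw_yield",
            "seed_setting_rate"),
  qpcr = c("sample_id", "gene", "well", "ct", "is_standard", "log10_copies"),
  otu = c("otu_id", "kingdom", "phylum", "genus")
)

#' Validate a dataset against the experiment design
#'
#' Checks referential integrity (treatment ids known), sign constraints
#' (volumes, counts), replicate counts, total-N consistency (TN at least the
#' larger of NH4-N and NO3-N, less a tolerance) and isotope abundance bounds
#' (between natural background - 0.05 and fertilizer abundance + 0.5 atom%).
#' Missing required columns are a hard error naming the column; everything
#' else is collected into a violations report.
#'
#' @param dataset a list with elements `leachate`, `soil`, `plant` and
#'   optionally `qpcr`, `otu` (as returned by [generate_experiment()] or
#'   [read_dataset()]).
#' @param config an [nfate_config()].
#' @param tn_tolerance slack (mg L-1) allowed in the TN >= NH4, NO3 check.
#' @return A data.frame of violations (table, row, message); zero rows iff
#'   the dataset is well-formed.
#' @export
validate_dataset <- function(dataset, config = nfate_config(),
                             tn_tolerance = 1e-6) {
  viol <- list()
  note <- function(table, row, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      table = table, row = row, message = message, stringsAsFactors = FALSE)
  }
  iso <- config$isotope
  ab_lo <- iso$natural_abundance - 0.05
  ab_hi <- iso$fertilizer_abundance + 0.5
  known <- config$design$treatment_id

  for (tab in intersect(names(.nfate_schemas), names(dataset))) {
    df <- dataset[[tab]]
    if (is.null(df)) next
    missing <- setdiff(.nfate_schemas[[tab]], names(df))
    if (length(missing)) {
      stop(sprintf("table '%s' is missing required column(s): %s",
                   tab, paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (tab %in% c("leachate", "soil", "plant")) {
      bad <- which(!(df$treatment_id %in% known))
      for (i in bad) note(tab, i, sprintf("unknown treatment_id '%s'",
                                          df$treatment_id[i]))
      bad <- which(df$atom_pct_15n < ab_lo | df$atom_pct_15n > ab_hi)
      for (i in bad) note(tab, i, sprintf(
        "atom_pct_15n %.4f outside [%.3f, %.3f]", df$atom_pct_15n[i],
        ab_lo, ab_hi))
    }
    if (tab == "leachate") {
      bad <- which(df$volume < 0)
      for (i in bad) note(tab, i, sprintf("negative volume %.3f", df$volume[i]))
      bad <- which(df$tn + tn_tolerance < pmax(df$nh4, df$no3))
      for (i in bad) note(tab, i, "tn below max(nh4, no3)")
    }
    if (tab == "plant") {
      bad <- which(df$dry_weight <= 0)
      for (i in bad) note(tab, i, "non-positive dry_weight")
      bad <- which(df$n_pct <= 0 | df$n_pct >= 5)
      for (i in bad) note(tab, i, sprintf("n_pct %.3f outside (0, 5)", df$n_pct[i]))
    }
    if (tab == "soil") {
      bad <- which(df$dry_mass <= 0)
      for (i in bad) note(tab, i, "non-positive dry_mass")
    }
  }

  # replicate counts: n = 3 expected per treatment in the plant table
  if (!is.null(dataset$plant)) {
    cnt <- table(dataset$plant$treatment_id)
    off <- names(cnt)[cnt != 3]
    for (tr in intersect(off, known)) {
      note("plant", NA_integer_,
           sprintf("treatment '%s' has %d replicates (expected 3)",
                   tr, cnt[[tr]]))
    }
  }

  if (length(viol)) do.call(rbind, viol) else
    data.frame(table = character(), row = integer(), message = character(),
               stringsAsFactors = FALSE)
}
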