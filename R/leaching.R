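#' Seasonal leachate volume of one device
#'
#' Sums the per-event drainage volumes V_i of a single (treatment,
#' replicate, depth port) series. Depth ports are never summed together:
#' both ports sample the same water column at different depths.
#'
#' @param volumes numeric vector of event volumes, L.
#' @return total volume V, L. An empty series returns 0 with a warning.
#' @export
total_leachate_volume <- function(volumes) {
  if (length(volumes) == 0) {
    warning("empty leachate series: total volume 0")
    return(0)
  }
  stopifnot(all(volumes >= 0))
  sum(volumes)
}

.annualize <- function(x, geom, annualize_mode = "upscale") {
  if (geom$season_fraction <= 0 || geom$devices_per_hectare <= 0) {
    stop("invalid geometry: season_fraction and devices_per_hectare must be > 0")
  }
  if (annualize_mode == "upscale") {
    (x / geom$season_fraction) * geom$devices_per_hectare * 1e-3
  } else {
    # alternative orientation, for sensitivity checks only
    (x / geom$season_fraction) / geom$devices_per_hectare * 1e-3
  }
}

#' Annualize a per-device leachate volume to t hm-2 yr-1
#'
#' V_L = (V / R_t) * R_s * 1e-3 where R_t is the season fraction of the year
#' and R_s the number of device footprints per hectare. Dividing by R_t
#' annualizes the seasonal total; multiplying by R_s upscales the device
#' footprint to a hectare; 1e-3 converts L (= kg of water) to tonnes.
#'
#' @param volume_l per-device seasonal volume, L.
#' @param geom a [device_geometry()].
#' @param annualize_mode see [nfate_config()].
#' @return t hm-2 yr-1.
#' @export
annualize_volume <- function(volume_l, geom, annualize_mode = "upscale") {
  stopifnot(all(volume_l >= 0))
  .annualize(volume_l, geom, annualize_mode)
}

#' Leached N mass of one device
#'
#' NLV = sum(C_i * V_i) * 1e-3 over sampling events: mg L-1 times L gives
#' mg, 1e-3 converts to g.
#'
#' @param conc_mg_l event concentrations, mg L-1 (TN, NH4-N or NO3-N).
#' @param volumes_l event volumes, L (same length).
#' @return N mass, g.
#' @export
leachate_n_mass <- function(conc_mg_l, volumes_l) {
  stopifnot(length(conc_mg_l) == length(volumes_l))
  bad <- which(is.na(conc_mg_l) & volumes_l > 0)
  if (length(bad)) {
    stop(sprintf("missing concentration on event(s) with volume > 0: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sum(conc_mg_l * volumes_l, na.rm = TRUE) * 1e-3
}

#' Blank-corrected total-N leaching loss rate
#'
#' NLL = (NLV_fertilized - NLV_control) / W_N * 100, where the control is
#' the mean leached N mass of the matched zero-N treatment under the same
#' irrigation mode. Negative values (possible under noise) are preserved,
#' not clamped; callers flag them.
#'
#' @param nlv_fertilized leached N mass of the fertilized device, g.
#' @param nlv_control mean leached N mass of the zero-N control, g.
#' @param applied_n applied N per device W_N, g; must be > 0.
#' @return loss rate, %.
#' @export
tn_leaching_loss_rate <- function(nlv_fertilized, nlv_control, applied_n) {
  if (any(applied_n <= 0)) {
    stop("loss rate undefined for zero applied N", call. = FALSE)
  }
  (nlv_fertilized - nlv_control) / applied_n * 100
}

#' Annualize a per-device leached N mass to kg hm-2 yr-1
#'
#' Same scaling as [annualize_volume()] applied to a mass: g per device and
#' season -> kg per hectare and year.
#'
#' @param nlv_g leached N mass, g per device.
#' @param geom a [device_geometry()].
#' @param annualize_mode see [nfate_config()].
#' @return kg hm-2 yr-1.
#' @export
annualize_n_loss <- function(nlv_g, geom, annualize_mode = "upscale") {
  stopifnot(all(nlv_g >= 0))
  .annualize(nlv_g, geom, annualize_mode)
}

#' Leaching summary for a whole experiment
#'
#' Per (treatment, replicate, depth port) and analyte: seasonal volume,
#' annualized volume, leached N mass and its annualized value; for
#' fertilized treatments at the configured loss port, the blank-corrected
#' TN leaching loss rate against the same-mode zero-N control mean.
#'
#' @param leachate leachate record table (see [validate_dataset()] schema).
#' @param config an [nfate_config()].
#' @return list with elements `per_device` (device x port x analyte rows)
#'   and `treatment` (treatment-level means at the loss port, with
#'   `loss_rate_pct` and a `flag` column marking negative rates).
#' @export
leaching_summary <- function(leachate, config = nfate_config()) {
  geom <- config$geometry
  design <- config$design
  analytes <- c(TN = "tn", NH4 = "nh4", NO3 = "no3")
  key <- interaction(leachate$treatment_id, leachate$replicate,
                     leachate$depth_port, drop = TRUE)
  rows <- lapply(split(leachate, key), function(d) {
    v <- total_leachate_volume(d$volume)
    out <- lapply(names(analytes), function(an) {
      m <- leachate_n_mass(d[[analytes[[an]]]], d$volume)
      data.frame(treatment_id = d$treatment_id[1], replicate = d$replicate[1],
                 depth_port = d$depth_port[1], analyte = an,
                 total_volume = v,
                 annualized_volume = annualize_volume(v, geom, config$annualize_mode),
                 n_mass = m,
                 annualized_n_loss = annualize_n_loss(m, geom, config$annualize_mode),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  per_device <- do.call(rbind, rows)
  rownames(per_device) <- NULL

  # treatment-level TN accounting at the configured exit port
  port <- config$loss_port
  tn <- per_device[per_device$analyte == "TN" & per_device$depth_port == port, ]
  agg <- aggregate(cbind(total_volume, annualized_volume, n_mass,
                         annualized_n_loss) ~ treatment_id, tn, mean)
  agg <- merge(design, agg, by = "treatment_id")
  ctrl <- agg[agg$n_fraction == 0, c("irrigation_mode", "n_mass")]
  names(ctrl)[2] <- "control_n_mass"
  agg <- merge(agg, ctrl, by = "irrigation_mode", all.x = TRUE)
  agg$applied_n_g <- kg_ha_to_g_device(agg$n_rate, geom)
  agg$loss_rate_pct <- NA_real_
  fert <- agg$n_fraction > 0
  agg$loss_rate_pct[fert] <- tn_leaching_loss_rate(
    agg$n_mass[fert], agg$control_n_mass[fert], agg$applied_n_g[fert])
  agg$flag <- ifelse(!is.na(agg$loss_rate_pct) & agg$loss_rate_pct < 0,
                     "negative_loss_rate", "")
  agg <- agg[order(agg$irrigation_mode, agg$n_fraction), ]
  rownames(agg) <- NULL
  list(per_device = per_device, treatment = agg)
}
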