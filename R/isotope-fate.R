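#' Nitrogen derived from fertilizer (isotope dilution)
#'
#' Ndff = (a - b) / (c - d) * 100, where a is the sample atom% 15N, b the
#' matched unfertilized control's atom%, c the fertilizer atom% and d the
#' natural background (0.368 atom%).
#'
#' @param a sample atom% 15N.
#' @param b control atom% 15N.
#' @param c_fert fertilizer atom% 15N.
#' @param d_nat natural background atom% 15N.
#' @param clamp if TRUE, clamp the result to [0, 100] (noise can push a
#'   slightly below b); clamping events are reported via a "clamped"
#'   attribute. The raw value is used downstream only when `clamp = FALSE`.
#' @return Ndff, %.
#' @export
ndff <- function(a, b, c_fert = 10.0, d_nat = 0.368, clamp = FALSE) {
  if (any(c_fert <= d_nat)) {
    stop("fertilizer abundance must exceed natural background", call. = FALSE)
  }
  val <- (a - b) / (c_fert - d_nat) * 100
  if (clamp) {
    clamped <- val < 0 | val > 100
    val <- pmin(pmax(val, 0), 100)
    attr(val, "clamped") <- clamped
  }
  val
}

# shared algebra of the three fate-rate equations: Ndff and the N content
# enter as fractions, the result is a percentage of applied labeled N
.n15_rate <- function(ndff_pct, e_pct, w_g, f_g) {
  if (any(f_g <= 0)) stop("applied labeled N must be > 0", call. = FALSE)
  (ndff_pct / 100) * (e_pct / 100) * w_g / f_g * 100
}

#' Plant 15N use efficiency
#'
#' NUE = Ndff * e_p * W_p / f * 100 with Ndff and the plant N content e_p
#' as fractions: the share of the applied labeled fertilizer N recovered in
#' plant biomass. Note e_p is the *total* N mass fraction of the plant;
#' the fertilizer-derived share is supplied by Ndff.
#'
#' @param ndff_pct plant Ndff, %.
#' @param n_pct plant total N content, % of dry mass.
#' @param dry_weight_g plant dry weight W_p, g.
#' @param applied_n_g applied labeled N f, g per device.
#' @return NUE, % of applied labeled N.
#' @export
plant_n15_use_efficiency <- function(ndff_pct, n_pct, dry_weight_g, applied_n_g) {
  .n15_rate(ndff_pct, n_pct, dry_weight_g, applied_n_g)
}

#' Soil 15N residue rate for one layer
#'
#' Same algebra as [plant_n15_use_efficiency()] with the layer's total N
#' content e_s (% of dry soil mass) and dry mass W_s (g per device layer).
#'
#' @param ndff_pct soil Ndff, %.
#' @param tn_pct soil total N content, % of dry mass.
#' @param dry_mass_g layer dry mass W_s, g per device.
#' @param applied_n_g applied labeled N f, g per device.
#' @return residue rate, % of applied labeled N.
#' @export
soil_n15_residue_rate <- function(ndff_pct, tn_pct, dry_mass_g, applied_n_g) {
  .n15_rate(ndff_pct, tn_pct, dry_mass_g, applied_n_g)
}

#' Leachate 15N loss rate
#'
#' Event-wise: the leachate N content e_L is derived from the measured
#' concentration C (mg L-1) as C / 1e4 percent by mass, and the leachate
#' mass W_L from the volume at 1000 g L-1. Event rates are summed, which
#' equals the rate of the summed labeled-N mass.
#'
#' @param ndff_pct per-event water Ndff, % (recycled if scalar).
#' @param conc_mg_l per-event N concentration, mg L-1.
#' @param volume_l per-event volume, L.
#' @param applied_n_g applied labeled N f, g per device.
#' @return loss rate, % of applied labeled N.
#' @export
leaching_n15_loss_rate <- function(ndff_pct, conc_mg_l, volume_l, applied_n_g) {
  e_l_pct <- conc_mg_l / 1e4            # mg L-1 -> % by mass of water
  w_l_g <- volume_l * 1000              # L -> g of water
  sum(.n15_rate(ndff_pct, e_l_pct, w_l_g, applied_n_g))
}

#' Assemble a fate partition for one treatment
#'
#' The unaccounted remainder (gaseous loss plus measurement closure error)
#' is 100 minus the measured components; components are preserved
#' unclamped, and a negative remainder is flagged, not silently absorbed.
#'
#' @param plant_pct,soil_0_30_pct,soil_30_60_pct,leach_pct measured
#'   components, % of applied labeled N.
#' @return one-row data.frame with the components, `unaccounted_pct` and a
#'   `flag` column.
#' @export
assemble_fate_partition <- function(plant_pct, soil_0_30_pct,
                                    soil_30_60_pct, leach_pct) {
  comp <- c(plant_pct, soil_0_30_pct, soil_30_60_pct, leach_pct)
  if (any(is.na(comp))) {
    nm <- c("plant_pct", "soil_0_30_pct", "soil_30_60_pct", "leach_pct")
    stop(sprintf("missing fate component(s): %s",
                 paste(nm[is.na(comp)], collapse = ", ")), call. = FALSE)
  }
  un <- 100 - sum(comp)
  data.frame(plant_pct = plant_pct, soil_0_30_pct = soil_0_30_pct,
             soil_30_60_pct = soil_30_60_pct, leach_pct = leach_pct,
             unaccounted_pct = un,
             flag = if (un < 0) "negative_unaccounted" else "",
             stringsAsFactors = FALSE)
}

# control atom% per compartment for one irrigation mode (mean of the
# matched zero-N treatment); falls back to the natural background
.control_abundance <- function(values, fallback) {
  if (length(values) == 0 || all(is.na(values))) fallback else
    mean(values, na.rm = TRUE)
}

#' Isotope fate partitions for a whole experiment
#'
#' Runs the isotope-dilution fate equations on the record tables: plant
#' uptake at harvest, soil residue per period and layer (against the
#' cumulative labeled N applied by that period), and leaching loss at the
#' configured exit port over the season. Control abundances b are the
#' matched zero-N treatment means (same irrigation mode; per period/layer
#' for soil, per port for water). Per-replicate fates are retained for the
#' statistics module; the treatment table aggregates replicates by
#' arithmetic mean.
#'
#' @param dataset list with `leachate`, `soil`, `plant` tables.
#' @param config an [nfate_config()].
#' @param split basal/tiller/panicle fractions of the seasonal N.
#' @return list with `per_replicate` (treatment x replicate fate rows),
#'   `treatment` (means + unaccounted remainder), `soil_periods`
#'   (per period/layer residue rates) and `leach_ports` (both ports).
#' @export
fate_partitions <- function(dataset, config = nfate_config(),
                            split = c(0.4, 0.3, 0.3)) {
  design <- config$design
  iso <- config$isotope
  geom <- config$geometry
  c_fert <- iso$fertilizer_abundance
  d_nat <- iso$natural_abundance
  cum_f <- cumsum(split)          # cumulative fraction applied by period
  periods <- c("after_basal", "after_tiller", "after_panicle")

  fert <- design[design$n_fraction > 0, ]
  out_rep <- list(); out_soil <- list(); out_leach <- list()

  for (i in seq_len(nrow(fert))) {
    tr <- fert$treatment_id[i]
    mode <- fert$irrigation_mode[i]
    ctrl_id <- design$treatment_id[design$irrigation_mode == mode &
                                     design$n_fraction == 0]
    f_total <- kg_ha_to_g_device(fert$n_rate[i], geom)

    # plant: control b from matched zero-N plants
    b_plant <- .control_abundance(
      dataset$plant$atom_pct_15n[dataset$plant$treatment_id == ctrl_id], d_nat)
    pl <- dataset$plant[dataset$plant$treatment_id == tr, ]

    # water: control b per port
    lw <- dataset$leachate
    for (rep_i in sort(unique(pl$replicate))) {
      p <- pl[pl$replicate == rep_i, ]
      nd_p <- ndff(p$atom_pct_15n, b_plant, c_fert, d_nat, clamp = TRUE)
      nue <- plant_n15_use_efficiency(as.numeric(nd_p), p$n_pct,
                                      p$dry_weight, f_total)

      # soil after panicle, both layers
      soil_rates <- sapply(c("0-30", "30-60"), function(layer) {
        b_soil <- .control_abundance(
          dataset$soil$atom_pct_15n[
            dataset$soil$treatment_id == ctrl_id &
              dataset$soil$period == "after_panicle" &
              dataset$soil$layer == layer], d_nat)
        s <- dataset$soil[dataset$soil$treatment_id == tr &
                            dataset$soil$replicate == rep_i &
                            dataset$soil$period == "after_panicle" &
                            dataset$soil$layer == layer, ]
        if (nrow(s) == 0) return(NA_real_)
        nd_s <- ndff(s$atom_pct_15n, b_soil, c_fert, d_nat, clamp = TRUE)
        sum(soil_n15_residue_rate(as.numeric(nd_s), s$tn_pct, s$dry_mass,
                                  f_total))
      })

      # leachate at the exit port over the season
      port <- config$loss_port
      b_wat <- .control_abundance(
        lw$atom_pct_15n[lw$treatment_id == ctrl_id & lw$depth_port == port],
        d_nat)
      w <- lw[lw$treatment_id == tr & lw$replicate == rep_i &
                lw$depth_port == port, ]
      nd_w <- ndff(w$atom_pct_15n, b_wat, c_fert, d_nat, clamp = TRUE)
      leach <- leaching_n15_loss_rate(as.numeric(nd_w), w$tn, w$volume, f_total)

      out_rep[[length(out_rep) + 1L]] <- data.frame(
        treatment_id = tr, replicate = rep_i, plant_pct = nue,
        soil_0_30_pct = soil_rates[["0-30"]],
        soil_30_60_pct = soil_rates[["30-60"]], leach_pct = leach,
        stringsAsFactors = FALSE)
    }

    # per-period soil residue rates (treatment means over replicates),
    # against cumulative applied N at that period
    for (pi in seq_along(periods)) {
      f_p <- f_total * cum_f[pi]
      for (layer in c("0-30", "30-60")) {
        b_soil <- .control_abundance(
          dataset$soil$atom_pct_15n[dataset$soil$treatment_id == ctrl_id &
                                      dataset$soil$period == periods[pi] &
                                      dataset$soil$layer == layer], d_nat)
        s <- dataset$soil[dataset$soil$treatment_id == tr &
                            dataset$soil$period == periods[pi] &
                            dataset$soil$layer == layer, ]
        if (nrow(s) == 0) next
        rate_by_rep <- sapply(split(s, s$replicate), function(sr) {
          nd <- ndff(sr$atom_pct_15n, b_soil, c_fert, d_nat, clamp = TRUE)
          sum(soil_n15_residue_rate(as.numeric(nd), sr$tn_pct, sr$dry_mass, f_p))
        })
        out_soil[[length(out_soil) + 1L]] <- data.frame(
          treatment_id = tr, period = periods[pi], layer = layer,
          residue_pct = mean(rate_by_rep), stringsAsFactors = FALSE)
      }
    }

    # both ports, treatment means, for the within-profile comparison
    for (port in c("upper", "lower")) {
      b_wat <- .control_abundance(
        lw$atom_pct_15n[lw$treatment_id == ctrl_id & lw$depth_port == port],
        d_nat)
      w <- lw[lw$treatment_id == tr & lw$depth_port == port, ]
      if (nrow(w) == 0) next
      rate_by_rep <- sapply(split(w, w$replicate), function(wr) {
        nd <- ndff(wr$atom_pct_15n, b_wat, c_fert, d_nat, clamp = TRUE)
        leaching_n15_loss_rate(as.numeric(nd), wr$tn, wr$volume, f_total)
      })
      out_leach[[length(out_leach) + 1L]] <- data.frame(
        treatment_id = tr, depth_port = port, leach_pct = mean(rate_by_rep),
        stringsAsFactors = FALSE)
    }
  }

  per_rep <- do.call(rbind, out_rep)
  agg <- aggregate(cbind(plant_pct, soil_0_30_pct, soil_30_60_pct, leach_pct)
                   ~ treatment_id, per_rep, mean)
  parts <- do.call(rbind, lapply(seq_len(nrow(agg)), function(j) {
    cbind(treatment_id = agg$treatment_id[j],
          assemble_fate_partition(agg$plant_pct[j], agg$soil_0_30_pct[j],
                                  agg$soil_30_60_pct[j], agg$leach_pct[j]))
  }))
  ord <- match(parts$treatment_id, design$treatment_id)
  parts <- parts[order(ord), ]
  rownames(parts) <- NULL
  list(per_replicate = per_rep, treatment = parts,
       soil_periods = do.call(rbind, out_soil),
       leach_ports = do.call(rbind, out_leach))
}
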