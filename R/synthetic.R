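# mean-one multiplicative lognormal noise
.ln_noise <- function(n, sigma) {
  if (sigma <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

#' Reference calibration of the synthetic experiment
#'
#' Per-treatment ground truth for the generator's default scenario: a two-
#' irrigation (TI/SWI) by four-N-rate paddy pot experiment on South China
#' red soil. Headline values are fixed (SWI-70 peak NUE 28.50%, minimum NUE
#' 19.28%; SWI-100 after-panicle 0-30 cm soil residue 38.25%; annualized TN
#' leaching losses 62.45 and 67.21 kg hm-2 yr-1 for SWI-100 and TI-100; TN
#' leaching loss rates spanning 4.60-6.32% with the TI high-N treatments at
#' the top; labeled-N leaching loss spanning 1.06-4.63% at the 30-60 cm port
#' and 0.99-2.95% at 0-30 cm; SWI-minus-TI NUE gains within 2.18-4.43% and
#' NLL reductions within 0.30-0.80%). Values for treatments between those
#' anchors are linear-in-rate interpolations and are marked
#' `interpolated = TRUE`: they define the scenario, they are not reported
#' measurements.
#'
#' The gaseous component closes every fate budget to exactly 100%.
#'
#' @param design treatment design, see [treatment_design()].
#' @param geometry a [device_geometry()] (fixes the annualization constant
#'   used to express per-device leached masses).
#' @return data.frame of class `synthetic_truth`, one row per treatment.
#' @export
reference_calibration <- function(design = treatment_design(),
                                  geometry = device_geometry()) {
  tr <- design
  key <- tr$treatment_id
  pick <- function(...) {
    v <- c(...)
    unname(v[key])
  }
  tr$nue_pct <- pick(`TI-0` = NA, `TI-40` = 19.28, `TI-70` = 25.195,
                     `TI-100` = 23.00, `SWI-0` = NA, `SWI-40` = 21.46,
                     `SWI-70` = 28.50, `SWI-100` = 27.43)
  tr$soil_0_30_pct <- pick(`TI-0` = NA, `TI-40` = 20.0, `TI-70` = 22.0,
                           `TI-100` = 24.0, `SWI-0` = NA, `SWI-40` = 30.0,
                           `SWI-70` = 34.0, `SWI-100` = 38.25)
  tr$soil_30_60_pct <- pick(`TI-0` = NA, `TI-40` = 18.0, `TI-70` = 20.0,
                            `TI-100` = 22.0, `SWI-0` = NA, `SWI-40` = 12.0,
                            `SWI-70` = 11.0, `SWI-100` = 10.0)
  tr$leach_pct <- pick(`TI-0` = NA, `TI-40` = 1.06, `TI-70` = 2.80,
                       `TI-100` = 4.63, `SWI-0` = NA, `SWI-40` = 1.31,
                       `SWI-70` = 1.90, `SWI-100` = 2.60)
  tr$leach_upper_pct <- pick(`TI-0` = NA, `TI-40` = 0.99, `TI-70` = 1.80,
                             `TI-100` = 2.95, `SWI-0` = NA, `SWI-40` = 1.20,
                             `SWI-70` = 1.75, `SWI-100` = 2.40)
  tr$gaseous_pct <- 100 - (tr$nue_pct + tr$soil_0_30_pct +
                             tr$soil_30_60_pct + tr$leach_pct)
  tr$nll_pct <- pick(`TI-0` = NA, `TI-40` = 5.20, `TI-70` = 6.10,
                     `TI-100` = 6.32, `SWI-0` = NA, `SWI-40` = 4.60,
                     `SWI-70` = 5.40, `SWI-100` = 5.80)

  # per-device seasonal TN mass at the exit port, anchored to the
  # annualized losses of the two full-rate treatments
  k_ann <- (1 / geometry$season_fraction) * geometry$devices_per_hectare * 1e-3
  anchor <- c(`TI-100` = 67.21, `SWI-100` = 62.45)  # kg hm-2 yr-1
  f_g <- kg_ha_to_g_device(tr$n_rate, geometry)
  nlv100 <- anchor / k_ann
  ctrl_nlv <- c(
    TI = unname(nlv100["TI-100"]) -
      tr$nll_pct[key == "TI-100"] / 100 * f_g[key == "TI-100"],
    SWI = unname(nlv100["SWI-100"]) -
      tr$nll_pct[key == "SWI-100"] / 100 * f_g[key == "SWI-100"])
  tr$nlv_g <- ctrl_nlv[tr$irrigation_mode] +
    ifelse(tr$n_fraction > 0, tr$nll_pct / 100 * f_g, 0)
  tr$annualized_tn_loss <- tr$nlv_g * k_ann
  tr$nlv_upper_g <- 1.2 * tr$nlv_g
  tr$interpolated <- !(key %in% c("TI-40", "TI-100", "SWI-40", "SWI-70",
                                  "SWI-100"))
  rownames(tr) <- NULL
  class(tr) <- c("synthetic_truth", class(tr))
  tr
}

#' Generator configuration
#'
#' Study conditions for the synthetic pot experiment: 8 treatments x 3
#' replicates, three labeled-urea applications (basal/tiller/panicle,
#' 40/30/30 split at 10 atom% 15N), weekly two-port leachate sampling over
#' a 126-day season, three soil sampling periods x two layers, harvest
#' plant records, qPCR plates and an OTU table. Leachate concentrations
#' follow pulse-decay dynamics (rate `lambda` per day) after each
#' fertilization, with a per-mode pulse amplitude (SWI responds more
#' sharply) and per-mode seasonal drainage volume (irrigation, not N rate,
#' drives percolation; SWI drains less). Noise is multiplicative mean-one
#' lognormal per measurement family (`sigma` elements volume, conc, atom,
#' plant, soil; additive normal cycles for `ct`); all default to 0, the
#' noise-free calibration conditions.
#'
#' @param design,geometry,isotope experiment description objects.
#' @param calibration a [reference_calibration()] truth table.
#' @param season_length days; `cadence` sampling interval, days.
#' @param fert_days day-of-season of basal/tiller/panicle applications.
#' @param split fraction of seasonal N per application.
#' @param volume_l per-mode seasonal drainage at the lower port, L.
#' @param amplitude per-mode concentration pulse amplitude.
#' @param lambda pulse decay rate, d-1.
#' @param sigma named list of noise scales.
#' @param soil_tn_pct,soil_dry_mass_g per-layer soil N content (%) and dry
#'   mass (g per device layer).
#' @param otu_depth reads per sample for the OTU table.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(design = treatment_design(),
                             geometry = device_geometry(),
                             isotope = isotope_constants(),
                             calibration = reference_calibration(design, geometry),
                             season_length = 126, cadence = 7,
                             fert_days = c(0, 25, 60),
                             split = c(0.4, 0.3, 0.3),
                             volume_l = c(TI = 58, SWI = 50),
                             amplitude = c(TI = 1.2, SWI = 2.2),
                             lambda = 0.05,
                             sigma = list(volume = 0, conc = 0, atom = 0,
                                          plant = 0, soil = 0, ct = 0),
                             soil_tn_pct = c(`0-30` = 0.105, `30-60` = 0.080),
                             soil_dry_mass_g = c(`0-30` = 26838, `30-60` = 28755),
                             otu_depth = 10000) {
  stopifnot(cadence >= 1, all(fert_days >= 0 & fert_days <= season_length))
  fate_cols <- c("nue_pct", "soil_0_30_pct", "soil_30_60_pct", "leach_pct",
                 "gaseous_pct")
  fert <- calibration$n_fraction > 0
  sums <- rowSums(calibration[fert, fate_cols])
  if (any(abs(sums - 100) > 1e-9) || any(calibration$gaseous_pct[fert] < 0)) {
    stop("infeasible calibration: fate fractions must be >= 0 and sum to 100",
         call. = FALSE)
  }
  structure(list(design = design, geometry = geometry, isotope = isotope,
                 calibration = calibration, season_length = season_length,
                 cadence = cadence, fert_days = fert_days, split = split,
                 volume_l = volume_l, amplitude = amplitude, lambda = lambda,
                 sigma = sigma, soil_tn_pct = soil_tn_pct,
                 soil_dry_mass_g = soil_dry_mass_g, otu_depth = otu_depth),
            class = "generator_config")
}

# Table-2-style plant phenotypes used as generator means
.plant_means <- data.frame(
  treatment_id = c("TI-0", "TI-40", "TI-70", "TI-100",
                   "SWI-0", "SWI-40", "SWI-70", "SWI-100"),
  plant_height = c(86.91, 91.02, 102.61, 104.38, 91.34, 93.85, 101.14, 105.61),
  grain_yield = c(6.21, 15.37, 42.91, 75.61, 5.68, 18.64, 45.15, 76.41),
  straw_yield = c(19.06, 46.17, 67.76, 88.06, 19.34, 45.52, 68.77, 94.45),
  seed_setting_rate = c(65.50, 70.00, 81.50, 85.00, 64.00, 68.00, 82.25, 88.00),
  n_pct = c(0.92, 0.96, 1.02, 1.16, 0.95, 1.22, 1.11, 1.14),
  stringsAsFactors = FALSE)

# concentration shape on the sampling days: baseline + post-pulse decay
.conc_shape <- function(days, fert_days, amplitude, lambda) {
  pulse <- rowSums(sapply(fert_days, function(fd) {
    ifelse(days >= fd, exp(-lambda * (days - fd)), 0)
  }))
  1 + amplitude * pulse
}

# residue trajectory: residue rate at each soil period as a multiple of the
# final (after-panicle) rate; TI accumulates early, SWI late
.soil_period_mult <- function(mode) {
  if (mode == "TI") c(after_basal = 1.05, after_tiller = 1.02,
                      after_panicle = 1.00)
  else c(after_basal = 0.60, after_tiller = 0.85, after_panicle = 1.00)
}

#' Generate a synthetic pot experiment with known ground truth
#'
#' Builds the record tables of a complete experiment so that running the
#' accounting pipeline forward on noise-free output returns the
#' calibration exactly: leachate concentration series are scaled so the
#' seasonal per-device N mass equals the calibrated value, and plant/soil/
#' water atom% 15N are obtained by inverting the isotope-dilution fate
#' equations at the calibrated fate fractions. Randomness only enters
#' through the noise scales; each table draws from its own seed stream
#' derived from `seed`, so requesting fewer tables never perturbs the
#' others.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param replicates replicates per treatment.
#' @param tables which record tables to generate.
#' @return list of class `nfate_dataset`: requested tables plus `truth`
#'   (the calibration with per-device bookkeeping) and `config`.
#' @export
generate_experiment <- function(config = generator_config(), seed = 0,
                                replicates = 3,
                                tables = c("leachate", "soil", "plant",
                                           "qpcr", "otu")) {
  tables <- match.arg(tables, several.ok = TRUE)
  cal <- config$calibration
  geom <- config$geometry
  iso <- config$isotope
  c_fert <- iso$fertilizer_abundance
  d_nat <- iso$natural_abundance
  days <- seq(config$cadence, config$season_length, by = config$cadence)
  f_g <- kg_ha_to_g_device(cal$n_rate, geom)
  sg <- config$sigma

  dataset <- list()

  if ("leachate" %in% tables) {
    set.seed(seed + 1L)
    rows <- list()
    for (i in seq_len(nrow(cal))) {
      mode <- cal$irrigation_mode[i]
      shape <- .conc_shape(days, config$fert_days,
                           config$amplitude[[mode]], config$lambda)
      for (port in c("upper", "lower")) {
        v_tot <- config$volume_l[[mode]] * if (port == "upper") 1.15 else 1
        nlv <- if (port == "lower") cal$nlv_g[i] else cal$nlv_upper_g[i]
        v_i <- rep(v_tot / length(days), length(days))
        s <- nlv * 1e3 / sum(shape * v_i)
        tn <- s * shape
        leach_target <- if (cal$n_fraction[i] > 0) {
          if (port == "lower") cal$leach_pct[i] else cal$leach_upper_pct[i]
        } else 0
        ndff_w <- if (leach_target > 0) leach_target / 100 * f_g[i] / nlv else 0
        atom <- d_nat + ndff_w * (c_fert - d_nat)
        for (r in seq_len(replicates)) {
          nv <- v_i * .ln_noise(length(v_i), sg$volume)
          cf <- .ln_noise(length(v_i), sg$conc)
          rows[[length(rows) + 1L]] <- data.frame(
            treatment_id = cal$treatment_id[i], replicate = r, day = days,
            depth_port = port, volume = nv, tn = tn * cf,
            nh4 = 0.7 * tn * cf, no3 = 0.2 * tn * cf,
            atom_pct_15n = atom * .ln_noise(length(v_i), sg$atom),
            stringsAsFactors = FALSE)
        }
      }
    }
    dataset$leachate <- do.call(rbind, rows)
  }

  if ("soil" %in% tables) {
    set.seed(seed + 2L)
    rows <- list()
    cum_f <- cumsum(config$split)
    periods <- c("after_basal", "after_tiller", "after_panicle")
    for (i in seq_len(nrow(cal))) {
      mode <- cal$irrigation_mode[i]
      mult <- .soil_period_mult(mode)
      for (p in seq_along(periods)) for (layer in c("0-30", "30-60")) {
        e_s <- config$soil_tn_pct[[layer]]
        w_s <- config$soil_dry_mass_g[[layer]]
        if (cal$n_fraction[i] > 0) {
          final <- if (layer == "0-30") cal$soil_0_30_pct[i] else
            cal$soil_30_60_pct[i]
          rate <- final * mult[[periods[p]]]
          f_p <- f_g[i] * cum_f[p]
          ndff_pct <- rate * f_p / ((e_s / 100) * w_s)
          atom <- d_nat + ndff_pct / 100 * (c_fert - d_nat)
        } else atom <- d_nat
        nh4 <- (8 + 20 * cal$n_fraction[i]) *
          (if (mode == "TI") 1.3 else 1.0) * (if (layer == "0-30") 1 else 0.8)
        no3 <- (3 + 9 * cal$n_fraction[i]) *
          (if (mode == "SWI") 1.3 else 1.0) * (if (layer == "0-30") 1 else 0.6)
        alk <- (30 + 15 * cal$n_fraction[i]) *
          (if (mode == "SWI") 1.15 else 1.0)
        for (r in seq_len(replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            treatment_id = cal$treatment_id[i], replicate = r,
            period = periods[p], layer = layer,
            tn_pct = e_s * .ln_noise(1, sg$soil),
            nh4 = nh4 * .ln_noise(1, sg$soil),
            no3 = no3 * .ln_noise(1, sg$soil),
            alkali_n = alk * .ln_noise(1, sg$soil),
            atom_pct_15n = atom * .ln_noise(1, sg$atom),
            dry_mass = w_s, stringsAsFactors = FALSE)
        }
      }
    }
    dataset$soil <- do.call(rbind, rows)
  }

  if ("plant" %in% tables) {
    set.seed(seed + 3L)
    rows <- list()
    pm <- .plant_means[match(cal$treatment_id, .plant_means$treatment_id), ]
    for (i in seq_len(nrow(cal))) {
      w_p <- pm$grain_yield[i] + pm$straw_yield[i]
      if (cal$n_fraction[i] > 0) {
        ndff_pct <- cal$nue_pct[i] * f_g[i] / ((pm$n_pct[i] / 100) * w_p)
        atom <- d_nat + ndff_pct / 100 * (c_fert - d_nat)
      } else atom <- d_nat
      for (r in seq_len(replicates)) {
        wn <- .ln_noise(1, sg$plant)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment_id = cal$treatment_id[i], replicate = r,
          dry_weight = w_p * wn, n_pct = pm$n_pct[i] * .ln_noise(1, sg$plant),
          atom_pct_15n = atom * .ln_noise(1, sg$atom),
          plant_height = pm$plant_height[i] * .ln_noise(1, sg$plant),
          grain_yield = pm$grain_yield[i] * wn,
          straw_yield = pm$straw_yield[i] * wn,
          seed_setting_rate = pm$seed_setting_rate[i] * .ln_noise(1, sg$plant),
          stringsAsFactors = FALSE)
      }
    }
    dataset$plant <- do.call(rbind, rows)
  }

  if ("qpcr" %in% tables) {
    dataset$qpcr <- generate_qpcr_plate(config, seed)
  }
  if ("otu" %in% tables) {
    dataset$otu <- generate_otu_table(config, seed, replicates)
  }

  dataset$truth <- cal
  dataset$config <- config
  class(dataset) <- "nfate_dataset"
  dataset
}

#' @export
print.nfate_dataset <- function(x, ...) {
  cat("Synthetic paddy pot experiment dataset\n")
  for (tab in intersect(c("leachate", "soil", "plant", "qpcr", "otu"),
                        names(x))) {
    cat(sprintf("  %-9s %5d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

# per-gene assay parameters: amplification efficiency and curve intercept
.qpcr_assays <- data.frame(
  gene = c("16S_bacteria", "16S_archaea", "amoA_bacteria", "amoA_archaea",
           "nirS", "nosZ"),
  efficiency = c(1.00, 0.97, 0.95, 0.93, 0.96, 0.94),
  intercept = c(38.5, 39.0, 39.5, 39.8, 39.2, 39.6),
  stringsAsFactors = FALSE)

# expected relative abundance of a functional gene for one sample
.qpcr_rel_abundance <- function(gene, mode, n_fraction, layer, period) {
  per_mult <- c(after_basal = 0.8, after_tiller = 1.0, after_panicle = 1.1)
  g <- 0.6 + 0.4 * n_fraction
  if (gene == "amoA_bacteria" || gene == "amoA_archaea") {
    base <- if (layer == "0-30") 4.30e-4 else 6.07e-4
    m <- if (mode == "SWI") 1.0 else 0.6
    rel <- base * m * g * per_mult[[period]]
    if (gene == "amoA_archaea") rel <- 10 * rel
    rel
  } else if (gene == "nirS") {
    5e-3 * (if (mode == "SWI") 1.2 else 1.0) * g * per_mult[[period]]
  } else {
    1e-3 * (if (mode == "SWI") 1.15 else 1.0) * g * per_mult[[period]]
  }
}

# true 16S copies per reaction by domain and layer
.qpcr_16s_copies <- function(gene, layer) {
  if (gene == "16S_bacteria") {
    if (layer == "0-30") 2e8 else 5e7
  } else {
    if (layer == "0-30") 5e6 else 2e6
  }
}

#' Generate a qPCR plate table
#'
#' Standards at the seven ten-fold levels 1e9 down to 1e3 (triplicate
#' wells) for each assay, sample wells in triplicate for every treatment x
#' layer x period, and no-template controls at cycle 40. Sample Ct values
#' come from each assay's configured standard curve, so the noise-free
#' plate round-trips the configured efficiencies and copy numbers exactly.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return qPCR table: sample_id, gene, well, ct, is_standard,
#'   log10_copies.
#' @export
generate_qpcr_plate <- function(config = generator_config(), seed = 0) {
  set.seed(seed + 4L)
  cal <- config$calibration
  sg <- config$sigma
  rows <- list()
  add <- function(sample_id, gene, ct, is_standard = FALSE,
                  log10_copies = NA_real_) {
    for (w in 1:3) {
      ct_w <- ct + if (sg$ct > 0) stats::rnorm(1, 0, sg$ct) else 0
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, gene = gene, well = w, ct = ct_w,
        is_standard = is_standard, log10_copies = log10_copies,
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(.qpcr_assays))) {
    g <- .qpcr_assays$gene[i]
    slope <- -1 / log10(1 + .qpcr_assays$efficiency[i])
    b0 <- .qpcr_assays$intercept[i]
    for (lg in 9:3) add("STD", g, b0 + slope * lg, TRUE, lg)
    add("NTC", g, 40)
    for (j in seq_len(nrow(cal))) for (layer in c("0-30", "30-60")) {
      for (period in c("after_basal", "after_tiller", "after_panicle")) {
        copies <- if (g %in% c("16S_bacteria", "16S_archaea")) {
          .qpcr_16s_copies(g, layer)
        } else {
          ref <- if (g == "amoA_archaea") "16S_archaea" else "16S_bacteria"
          .qpcr_rel_abundance(g, cal$irrigation_mode[j], cal$n_fraction[j],
                              layer, period) * .qpcr_16s_copies(ref, layer)
        }
        sid <- paste(cal$treatment_id[j], layer, period, sep = "|")
        add(sid, g, b0 + slope * log10(copies))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# deterministic OTU inventory: phyla, genera and within-phylum weights
.otu_inventory <- function() {
  phyla <- list(
    Proteobacteria = c("Anaeromyxobacter", "Geobacter", "Sphingomonas",
                       "Nitrosomonas", "Bradyrhizobium", "Dechloromonas"),
    Firmicutes = c("Bacillus", "Clostridium", "Paenibacillus", "Sporomusa"),
    Chloroflexi = c("Anaerolinea", "Levilinea", "Chloroflexus"),
    Acidobacteria = c("Candidatus_Solibacter", "Acidobacterium", "Geothrix"),
    Actinobacteria = c("Streptomyces", "Arthrobacter", "Mycobacterium"),
    Bacteroidetes = c("Flavobacterium", "Chitinophaga", "Paludibacter"),
    Nitrospirae = c("Nitrospira", "Leptospirillum"),
    Planctomycetes = c("Gemmata", "Pirellula"))
  rows <- list()
  k <- 0
  for (ph in names(phyla)) {
    genera <- phyla[[ph]]
    for (gi in seq_along(genera)) {
      for (o in 1:2) {  # two OTUs per genus
        k <- k + 1
        rows[[k]] <- data.frame(
          otu_id = sprintf("OTU%03d", k), kingdom = "Bacteria", phylum = ph,
          genus = genera[gi], weight = 1 / (gi + o - 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Expected phylum profile of one sample
#'
#' The generator's community model: a fixed base composition with the
#' Proteobacteria share set directly (0.2147 + 0.04 x n_fraction in SWI
#' surface soil, so SWI-100 at 0-30 cm is exactly 25.47%), a per-mode
#' Firmicutes share (SWI 0.12, TI 0.08), and the remaining phyla scaled
#' proportionally to fill the rest.
#'
#' @param irrigation_mode "TI" or "SWI".
#' @param n_fraction N rate fraction (0-1).
#' @param layer "0-30" or "30-60".
#' @return named numeric vector of phylum proportions summing to 1.
#' @export
otu_profile <- function(irrigation_mode, n_fraction, layer) {
  base <- c(Proteobacteria = 0.22, Chloroflexi = 0.16, Acidobacteria = 0.14,
            Firmicutes = 0.10, Actinobacteria = 0.10, Bacteroidetes = 0.09,
            Nitrospirae = 0.05, Planctomycetes = 0.04)
  prot <- if (irrigation_mode == "SWI") 0.2147 + 0.04 * n_fraction
          else 0.19 + 0.03 * n_fraction
  if (layer != "0-30") prot <- 0.8 * prot
  firm <- if (irrigation_mode == "SWI") 0.12 else 0.08
  rest <- names(base)[!names(base) %in% c("Proteobacteria", "Firmicutes")]
  prof <- base
  prof["Proteobacteria"] <- prot
  prof["Firmicutes"] <- firm
  prof[rest] <- base[rest] / sum(base[rest]) * (1 - prot - firm)
  prof
}

#' Generate a wide OTU count table
#'
#' One multinomial draw of `otu_depth` reads per sample (treatment x layer
#' x replicate), with per-sample OTU probabilities given by the phylum
#' profile of [otu_profile()] distributed over the phylum's OTUs by fixed
#' within-phylum weights (Bacillus, Clostridium and Anaeromyxobacter
#' upweighted 1.5-fold under SWI).
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param replicates replicates per treatment.
#' @return wide data.frame: otu_id, kingdom, phylum, genus, then one count
#'   column per sample (named treatment|layer|replicate).
#' @export
generate_otu_table <- function(config = generator_config(), seed = 0,
                               replicates = 3) {
  set.seed(seed + 5L)
  cal <- config$calibration
  inv <- .otu_inventory()
  counts <- list()
  for (i in seq_len(nrow(cal))) for (layer in c("0-30", "30-60")) {
    prof <- otu_profile(cal$irrigation_mode[i], cal$n_fraction[i], layer)
    w <- inv$weight
    boost <- inv$genus %in% c("Bacillus", "Clostridium", "Anaeromyxobacter") &
      cal$irrigation_mode[i] == "SWI"
    w[boost] <- w[boost] * 1.5
    p <- numeric(nrow(inv))
    for (ph in names(prof)) {
      idx <- inv$phylum == ph
      p[idx] <- prof[[ph]] * w[idx] / sum(w[idx])
    }
    for (r in seq_len(replicates)) {
      sid <- paste(cal$treatment_id[i], layer, r, sep = "|")
      counts[[sid]] <- as.integer(stats::rmultinom(1, config$otu_depth, p))
    }
  }
  cbind(inv[, c("otu_id", "kingdom", "phylum", "genus")],
        as.data.frame(counts, check.names = FALSE))
}

#' Extract the samples x OTUs count matrix from a wide OTU table
#'
#' @param otu wide OTU table as produced by [generate_otu_table()].
#' @return integer matrix with samples in rows (sample ids as rownames)
#'   and OTUs in columns.
#' @export
otu_counts <- function(otu) {
  meta <- intersect(c("otu_id", "kingdom", "phylum", "genus"), names(otu))
  m <- t(as.matrix(otu[, setdiff(names(otu), meta), drop = FALSE]))
  colnames(m) <- otu$otu_id
  m
}
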