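test_that("the reference calibration is internally consistent", {
  truth <- reference_calibration()
  fert <- truth[truth$n_fraction > 0, ]
  sums <- fert$nue_pct + fert$soil_0_30_pct + fert$soil_30_60_pct +
    fert$leach_pct + fert$gaseous_pct
  expect_equal(sums, rep(100, 6), tolerance = 1e-12)
  expect_true(all(fert$gaseous_pct > 0))
  # SWI improves NUE by 2.18-4.43 and cuts the TN loss rate by 0.30-0.80
  # at matched rates; loss rates span 4.60-6.32 with TI-70/TI-100 on top
  for (fr in c(0.4, 0.7, 1.0)) {
    ti <- fert[fert$irrigation_mode == "TI" & fert$n_fraction == fr, ]
    sw <- fert[fert$irrigation_mode == "SWI" & fert$n_fraction == fr, ]
    expect_true(sw$nue_pct - ti$nue_pct >= 2.18 - 1e-9 &&
                  sw$nue_pct - ti$nue_pct <= 4.43 + 1e-9)
    expect_true(ti$nll_pct - sw$nll_pct >= 0.30 - 1e-9 &&
                  ti$nll_pct - sw$nll_pct <= 0.80 + 1e-9)
  }
  expect_equal(range(fert$nll_pct), c(4.60, 6.32))
  expect_equal(min(fert$nue_pct), 19.28)
  expect_equal(max(fert$nue_pct), 28.50)
  expect_true(all(fert$leach_pct >= 1.06 & fert$leach_pct <= 4.63))
})

test_that("infeasible calibrations are rejected before sampling", {
  bad <- reference_calibration()
  bad$nue_pct[bad$treatment_id == "TI-100"] <- 90
  bad$gaseous_pct <- 100 - (bad$nue_pct + bad$soil_0_30_pct +
                              bad$soil_30_60_pct + bad$leach_pct)
  expect_error(generator_config(calibration = bad), "infeasible")
})

test_that("identical seed and config give byte-identical CSV output", {
  cfg <- noisy_config(0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(generate_experiment(cfg, seed = 0), d1)
  write_dataset(generate_experiment(cfg, seed = 0), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seeds perturb a noisy dataset
  d3 <- withr::local_tempdir()
  write_dataset(generate_experiment(cfg, seed = 1), d3)
  expect_false(identical(readLines(file.path(d1, "leachate.csv")),
                         readLines(file.path(d3, "leachate.csv"))))
})

test_that("table-specific seed streams do not interact", {
  full <- generate_experiment(noisy_config(0.1), seed = 2)
  part <- generate_experiment(noisy_config(0.1), seed = 2,
                              tables = c("leachate", "plant"))
  expect_identical(part$leachate, full$leachate)
  expect_identical(part$plant, full$plant)
})

test_that("every generated device conserves the applied labeled N", {
  ds <- nf_dataset()
  truth <- ds$truth
  cfg <- nfate_config()
  geom <- cfg$geometry
  fp <- fate_partitions(ds, cfg)
  m <- merge(fp$per_replicate, truth, by = "treatment_id")
  recovered <- m$plant_pct + m$soil_0_30_pct.x + m$soil_30_60_pct.x +
    m$leach_pct.x
  applied <- kg_ha_to_g_device(m$n_rate, geom)
  # measured + gaseous 15N mass equals the applied mass, device by device
  lhs <- (recovered + m$gaseous_pct) / 100 * applied
  expect_equal(lhs, applied, tolerance = 1e-10)
})

test_that("generated concentrations stay inside the calibrated ranges", {
  ds <- nf_dataset()
  lw <- ds$leachate
  ranges <- list(`SWI-100` = c(1.30, 5.41), `TI-100` = c(1.89, 5.25))
  for (tr in names(ranges)) {
    x <- lw$tn[lw$treatment_id == tr & lw$depth_port == "lower"]
    expect_gte(min(x), ranges[[tr]][1])
    expect_lte(max(x), ranges[[tr]][2])
  }
  # concentrations pulse after each fertilization then decay
  one <- lw[lw$treatment_id == "SWI-100" & lw$replicate == 1 &
              lw$depth_port == "lower", ]
  fd <- ds$config$fert_days[3]
  pre <- one$tn[max(which(one$day <= fd))]
  post <- one$tn[min(which(one$day > fd))]
  expect_gt(post, pre)
})

test_that("noise scales increase the spread of recovered efficiencies", {
  nue_sd <- sapply(c(0.02, 0.15), function(s) {
    vals <- sapply(1:12, function(i) {
      ds <- generate_experiment(noisy_config(s), seed = 100 + i,
                                tables = c("leachate", "soil", "plant"))
      fp <- fate_partitions(ds)
      fp$treatment$plant_pct[fp$treatment$treatment_id == "SWI-70"]
    })
    sd(vals)
  })
  expect_lt(nue_sd[1], nue_sd[2])
})

test_that("noise-free qPCR standards round-trip configured efficiencies", {
  ds <- nf_dataset()
  qa <- qpcr_abundance(ds$qpcr)
  # the bacterial 16S assay is configured at perfect doubling
  expect_equal(qa$curves[["16S_bacteria"]]$efficiency, 1.0, tolerance = 1e-9)
  expect_equal(qa$curves[["amoA_bacteria"]]$efficiency, 0.95,
               tolerance = 1e-9)
  std <- ds$qpcr[ds$qpcr$is_standard & ds$qpcr$gene == "nirS", ]
  expect_setequal(unique(std$log10_copies), 3:9)
})
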