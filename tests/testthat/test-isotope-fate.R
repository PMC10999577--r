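test_that("isotope-dilution Ndff behaves at its anchors", {
  expect_equal(ndff(10.0, 0.368, 10.0, 0.368), 100)
  expect_equal(ndff(0.368, 0.368), 0)
  # (1.3312 - 0.368) / (10 - 0.368) * 100 = 0.9632 / 9.632 * 100
  expect_equal(ndff(1.3312, 0.368), 10.0)
  expect_error(ndff(1, 0.368, c_fert = 0.3, d_nat = 0.368), "exceed")
})

test_that("Ndff is invariant under joint affine rescaling", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.4, 9); b <- 0.368; cc <- 10; d <- 0.368
    s <- runif(1, 0.1, 5); t0 <- runif(1, -1, 1)
    expect_equal(ndff(s * a + t0, s * b + t0, s * cc + t0, s * d + t0),
                 ndff(a, b, cc, d))
  }
})

test_that("Ndff clamping flags but bounds out-of-range values", {
  v <- ndff(0.30, 0.368, clamp = TRUE)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clamped"))
})

test_that("plant 15N use efficiency follows the percent-to-fraction algebra", {
  expect_equal(plant_n15_use_efficiency(50, 1, 100, 1), 50)
  expect_equal(plant_n15_use_efficiency(0, 1, 100, 1), 0)
  expect_equal(plant_n15_use_efficiency(50, 1, 200, 1),
               2 * plant_n15_use_efficiency(50, 1, 100, 1))
  expect_error(plant_n15_use_efficiency(50, 1, 100, 0), "> 0")
})

test_that("soil residue rate shares the same algebra and is additive", {
  expect_equal(soil_n15_residue_rate(10, 0.1, 50000, 10), 50)
  expect_equal(soil_n15_residue_rate(10, 0.1, 0, 10), 0)
  # joint computation equals pooled layers at identical ndff and content
  r1 <- soil_n15_residue_rate(10, 0.1, 20000, 10)
  r2 <- soil_n15_residue_rate(10, 0.1, 30000, 10)
  expect_equal(r1 + r2, soil_n15_residue_rate(10, 0.1, 50000, 10))
})

test_that("leachate loss rate converts mg/L to a mass-percent content", {
  # C = 5 mg/L -> e_L = 5e-4 %; V = 2 L -> W_L = 2000 g
  expect_equal(leaching_n15_loss_rate(100, 5, 2, 1), 1.0)
  expect_equal(leaching_n15_loss_rate(0, 5, 2, 1), 0)
  # event-wise sum equals rate of summed labeled mass
  ev <- leaching_n15_loss_rate(c(40, 60), c(3, 4), c(1, 2), 2)
  pooled <- (0.4 * 3 * 1 + 0.6 * 4 * 2) * 1e-3 / 2 * 100
  expect_equal(ev, pooled)
})

test_that("fate partition closes to 100 and flags negatives", {
  fp <- assemble_fate_partition(28.50, 38.25, 10.00, 1.31)
  expect_equal(fp$unaccounted_pct, 21.94)
  expect_equal(assemble_fate_partition(0, 0, 0, 0)$unaccounted_pct, 100)
  expect_equal(assemble_fate_partition(40, 30, 20, 10)$unaccounted_pct, 0)
  expect_equal(assemble_fate_partition(50, 40, 20, 5)$flag,
               "negative_unaccounted")
  expect_error(assemble_fate_partition(28.5, NA, 10, 1.31), "soil_0_30_pct")
})

test_that("noise-free fate pipeline recovers the generator truth exactly", {
  p <- nf_pipeline()
  truth <- nf_dataset()$truth
  m <- merge(p$fate$treatment, truth, by = "treatment_id")
  expect_equal(m$plant_pct, m$nue_pct, tolerance = 1e-8)
  expect_equal(m$soil_0_30_pct.x, m$soil_0_30_pct.y, tolerance = 1e-8)
  expect_equal(m$soil_30_60_pct.x, m$soil_30_60_pct.y, tolerance = 1e-8)
  expect_equal(m$leach_pct.x, m$leach_pct.y, tolerance = 1e-8)
  expect_equal(m$unaccounted_pct, m$gaseous_pct, tolerance = 1e-8)
  # upper-port loss rates recover their own calibration
  up <- p$fate$leach_ports
  up <- up[up$depth_port == "upper", ]
  m2 <- merge(up, truth, by = "treatment_id")
  expect_equal(m2$leach_pct.x, m2$leach_upper_pct, tolerance = 1e-8)
})

test_that("zero-N treatments show natural abundance and zero Ndff", {
  ds <- nf_dataset()
  for (tab in c("leachate", "soil", "plant")) {
    ctrl <- ds[[tab]][ds[[tab]]$treatment_id %in% c("TI-0", "SWI-0"), ]
    expect_true(all(ctrl$atom_pct_15n == 0.368))
  }
})
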