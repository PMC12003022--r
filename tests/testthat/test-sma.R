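make_assay <- function(ch4_mL, time_d = seq(0, 3, by = 0.25), substrate = "acetate",
                       vs = 0.04, cal = 0.5, hcf = 1.2, ch4_frac = 0.6,
                       id = "b1", fraction = "E") {
  sma_assay(bottle_id = id, fraction_label = fraction, substrate = substrate,
            vs_mass_g = vs, time_d = time_d,
            pressure_mV = ch4_mL / ch4_frac / (cal * hcf),
            ch4_fraction = rep(ch4_frac, length(time_d)),
            calibration_mL_per_mV = cal, headspace_correction = hcf)
}

test_that("pressure-to-volume conversion is linear", {
  expect_equal(pressure_to_volume(100, 0.1, 1.0), 10)
  expect_equal(pressure_to_volume(0, 0.37, 2.2), 0)
  expect_equal(pressure_to_volume(50, 0.1, 2), 2 * pressure_to_volume(50, 0.1, 1))
  expect_error(pressure_to_volume(-1, 0.1), "negative")
  expect_error(pressure_to_volume(10, 0), "slope")
})

test_that("methane accumulation applies CH4 fraction and background", {
  t <- 0:5
  a <- make_assay(10 * t / 5, time_d = t, ch4_frac = 0.5)
  acc <- methane_accumulation(a)
  expect_equal(acc$ch4_mL[length(t)], 10)  # 50 % CH4 of 20 mL biogas

  # identical assay and control cancel exactly
  acc0 <- methane_accumulation(a, a)
  expect_equal(acc0$ch4_mL, rep(0, length(t)))

  # planted production 8 mL/d with 1 mL/d background -> net 7 mL/d
  prod <- make_assay(9 * t, time_d = t)   # total observed = 8 + 1 mL/d
  ctrl <- make_assay(1 * t, time_d = t, substrate = "control_none")
  net <- methane_accumulation(prod, ctrl)
  expect_equal(diff(net$ch4_mL) / diff(t), rep(8, length(t) - 1))

  short <- make_assay(1 * t[1:4], time_d = t[1:4], substrate = "control_none")
  expect_error(methane_accumulation(prod, short), "span")
})

test_that("soluble-substrate SMA rate is max window slope over VS", {
  t <- seq(0, 3, by = 0.25)
  a <- make_assay(10 * t, time_d = t)  # 10 mL CH4/d, vs 0.04 g
  r <- sma_rate(a)
  expect_equal(r$rate_mL_gVS_d, 250)
  expect_equal(r$r_squared, 1)

  # zero production: rate 0, r-squared reported as 0
  z <- sma_rate(make_assay(rep(0, length(t)), time_d = t))
  expect_equal(z$rate_mL_gVS_d, 0)
  expect_equal(z$r_squared, 0)

  # time-grid offset invariance
  a2 <- make_assay(10 * t, time_d = t + 17.3)
  expect_equal(sma_rate(a2)$rate_mL_gVS_d, 250)

  # background subtraction of a bottle against itself gives exactly 0
  expect_equal(sma_rate(a, a)$rate_mL_gVS_d, 0)

  expect_error(sma_rate(make_assay(c(0, 1, 2), time_d = 0:2)), "at least")
  expect_error(sma_rate(make_assay(10 * t, time_d = t, substrate = "H2CO2")),
               "sma_rate_h2")
})

test_that("planted slope is recovered within 2 % at 2 % noise (whole-phase fit)", {
  t <- seq(0, 5, by = 0.25)
  set.seed(99)
  clean <- 10 * t + 1  # strictly positive signal, pure linear phase
  noisy <- clean * (1 + rnorm(length(t), 0, 0.02))
  a <- make_assay(noisy, time_d = t)
  r <- sma_rate(a, window = length(t))
  expect_equal(r$rate_mL_gVS_d, 250, tolerance = 0.02)
  # zero noise recovered to < 0.1 %
  expect_equal(sma_rate(make_assay(clean, time_d = t))$rate_mL_gVS_d, 250,
               tolerance = 1e-3)
})

test_that("H2/CO2 rates apply the 4:1 stoichiometry", {
  t <- seq(0, 3, by = 0.25)
  start <- 100
  # 22.4 mL H2 (STP) consumed per day = 1 mmol/d -> 0.25 mmol CH4 = 5.6 mL/d
  h <- sma_assay("h", "E", "H2CO2", vs_mass_g = 0.04, time_d = t,
                 pressure_mV = (start - 22.4 * t) / (0.5 * 1.2),
                 ch4_fraction = rep(0, length(t)),
                 calibration_mL_per_mV = 0.5, headspace_correction = 1.2)
  r <- sma_rate_h2(h)
  expect_equal(r$rate_mL_gVS_d, 5.6 / 0.04)  # 140
  # 4 mL H2 consumed total -> 1 mL CH4 equivalent accumulates
  flat <- sma_assay("h0", "E", "H2CO2", vs_mass_g = 0.04, time_d = t,
                    pressure_mV = rep(start, length(t)),
                    ch4_fraction = rep(0, length(t)),
                    calibration_mL_per_mV = 1, headspace_correction = 1)
  expect_equal(sma_rate_h2(flat)$rate_mL_gVS_d, 0)
  expect_error(sma_rate_h2(make_assay(10 * t, time_d = t)), "substrate")
})

test_that("synthetic assays recover planted rates and the medium-size peak", {
  sm <- generate_sma(generator_config(seed = 21))
  res <- sma_rate_matrix(sm$assays)
  rel <- abs(res$rates[, colnames(sm$truth)] - sm$truth) / sm$truth
  expect_lt(max(rel), 1e-3)
  expect_equal(names(which.max(res$rates[, "H2CO2"])), "F")
  # hydrogen is the most active substrate in every fraction
  expect_true(all(res$rates[, "H2CO2"] > res$rates[, "acetate"]))
})
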