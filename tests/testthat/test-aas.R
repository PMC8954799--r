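test_that("calibration recovers an exact line through blank-corrected signals", {
  std <- data.frame(concentration = c(1, 2, 3), signal = c(2, 4, 6))
  cal <- fit_calibration(std, blanks = 0, metal = "X")
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-12)
  # single zero blank: LoD from the (zero) line residuals
  expect_equal(cal$lod, 0, tolerance = 1e-12)
  expect_true(cal$lod_ok)
})

test_that("calibration matches the closed-form least-squares solution", {
  # Cd standard series with noisy synthetic signals
  conc <- c(2, 4, 6)
  set.seed(5)
  blanks <- rnorm(5, 0.05, 0.005)
  signal <- 0.05 + 1.7 * conc + c(-0.08, 0.03, 0.05)
  cal <- fit_calibration(data.frame(concentration = conc, signal = signal),
                         blanks, metal = "Cd")
  # normal-equation oracle on blank-corrected signals
  y <- signal - mean(blanks)
  slope_ref <- sum((conc - mean(conc)) * (y - mean(y))) /
    sum((conc - mean(conc))^2)
  intercept_ref <- mean(y) - slope_ref * mean(conc)
  expect_equal(cal$slope, slope_ref, tolerance = 1e-10)
  expect_equal(cal$intercept, intercept_ref, tolerance = 1e-10)
  # LoD from blank spread: 3 sd / slope, below the lowest standard
  expect_equal(cal$lod, 3 * sd(blanks) / cal$slope, tolerance = 1e-12)
  expect_true(cal$lod_ok)
})

test_that("LoD falls back to the residual rule and flags bad lines", {
  conc <- c(2, 4, 6)
  signal <- c(4.2, 7.8, 12.3)
  cal2 <- fit_calibration(data.frame(concentration = conc, signal = signal),
                          blanks = c(0.1, 0.12), metal = "X")
  expect_equal(cal2$lod, 3.3 * cal2$residual_sd / cal2$slope,
               tolerance = 1e-12)
  # huge blank spread pushes LoD above the lowest standard
  expect_warning(
    bad <- fit_calibration(data.frame(concentration = conc, signal = signal),
                           blanks = c(-3, 0, 3), metal = "X"),
    "LoD.*exceeds")
  expect_false(bad$lod_ok)
  expect_error(fit_calibration(data.frame(concentration = c(2, 2, 2),
                                          signal = signal), 0),
               "distinct")
  expect_error(fit_calibration(data.frame(concentration = conc,
                                          signal = rev(signal)), 0),
               "non-positive")
})

test_that("signal-to-solution applies blank, intercept, slope and dilution", {
  cal <- make_calibration("X", slope = 2, intercept = 0, lod = 0.5,
                          standard_range = c(1, 10))
  out <- signal_to_solution(10, 0, cal, dilution = 5)
  expect_equal(out$concentration, 25)
  expect_false(out$below_lod)
  # peak equal to blank reads zero and is below LoD
  zero <- signal_to_solution(3, 3, cal)
  expect_equal(zero$concentration, 0)
  expect_true(zero$below_lod)
  # negative net signal flags, does not error
  neg <- signal_to_solution(1, 3, cal)
  expect_lt(neg$concentration, 0)
  expect_true(neg$below_lod)
  expect_error(signal_to_solution(1, 0, cal, dilution = 0.5), "dilution")
  # linearity: doubling the net signal doubles the concentration
  a <- signal_to_solution(4, 0, cal)$concentration
  b <- signal_to_solution(8, 0, cal)$concentration
  expect_equal(b, 2 * a)
})

test_that("a diluted and an undiluted aliquot agree after dilution correction", {
  cal <- make_calibration("X", slope = 3, intercept = 0.2, blank_mean = 0.5,
                          standard_range = c(1, 40))
  true_conc <- 12
  signal_undiluted <- cal$blank_mean + cal$intercept + cal$slope * true_conc
  signal_diluted <- cal$blank_mean + cal$intercept + cal$slope * (true_conc / 4)
  c1 <- signal_to_solution(signal_undiluted, cal$blank_mean, cal)$concentration
  c2 <- signal_to_solution(signal_diluted, cal$blank_mean, cal,
                           dilution = 4)$concentration
  expect_equal(c1, true_conc, tolerance = 1e-12)
  expect_equal(c2, true_conc, tolerance = 1e-12)
})

test_that("solution-to-tissue follows the digest protocol arithmetic", {
  # 100 mg of powder in 4 mL of digest: 1 mg/L -> 40 mg/kg
  expect_equal(solution_to_tissue(1, 0.004, 1e-4), 40)
  expect_equal(solution_to_tissue(0, 0.004, 1e-4), 0)
  # homogeneous of degree 1 in concentration
  expect_equal(solution_to_tissue(3.7, 0.004, 1e-4),
               3.7 * solution_to_tissue(1, 0.004, 1e-4))
  # invariant under joint scaling of volume and mass
  expect_equal(solution_to_tissue(2, 0.008, 2e-4),
               solution_to_tissue(2, 0.004, 1e-4))
  expect_error(solution_to_tissue(1, 0, 1e-4), "positive")
})

test_that("QC windows are closed intervals at the stated limits", {
  r <- spike_recovery(1100, 100, 1000)
  expect_equal(r$percent, 100)
  expect_true(r$pass)
  expect_true(spike_recovery(1050, 100, 1000)$pass)   # 95%
  expect_false(spike_recovery(980, 100, 1000)$pass)   # 88%
  expect_true(spike_recovery(1000, 100, 1000)$pass)   # exactly 90%
  expect_true(spike_recovery(1200, 100, 1000)$pass)   # exactly 110%
  expect_error(spike_recovery(1, 0, 0), "positive")

  expect_true(control_check(10, 10)$pass)     # 100%
  expect_false(control_check(10.6, 10)$pass)  # 106%
  expect_true(control_check(9.5, 10)$pass)    # inclusive 95%
  expect_true(control_check(10.5, 10)$pass)   # inclusive 105%
  expect_false(control_check(9.4, 10)$pass)
  expect_error(control_check(1, -1), "positive")
})

test_that("forward-simulated records quantify back to the true tissue values", {
  study <- simulate_study(seed = 23, noise_sd = 0)
  cals <- list(
    Cd = make_calibration("Cd", slope = 1.5, intercept = 0.1,
                          blank_mean = 0.3, standard_range = c(2, 6),
                          unit_scale = 1e-3),
    Zn = make_calibration("Zn", slope = 4, intercept = 0,
                          standard_range = c(0.1, 0.8), unit_scale = 1)
  )
  rec <- simulate_aas_records(study$uptake, cals, signal_sd = 0)
  expect_setequal(unique(rec$metal), c("Cd", "Zn"))
  # dilution keeps every analysed concentration inside the standard range
  measured <- with(rec, {
    cal_slope <- ifelse(metal == "Cd", cals$Cd$slope, cals$Zn$slope)
    cal_int <- ifelse(metal == "Cd", cals$Cd$intercept, cals$Zn$intercept)
    ((peak_area - blank_area) - cal_int) / cal_slope
  })
  top <- ifelse(rec$metal == "Cd", 6, 0.8)
  expect_true(all(measured <= top + 1e-9))

  q <- quantify_aas(rec, cals)
  truth <- c(study$uptake$Cd, study$uptake$Zn)
  got <- c(q$tissue_mg_per_kg[q$metal == "Cd"],
           q$tissue_mg_per_kg[q$metal == "Zn"])
  expect_equal(got, truth, tolerance = 1e-9)
  expect_true(all(q$height_ok))
})

test_that("blank-level records are flagged below the limit of detection", {
  cal <- make_calibration("Cd", slope = 2, lod = 0.5,
                          standard_range = c(2, 6))
  rec <- tibble::tibble(sample_id = "blank1", metal = "Cd",
                        peak_area = cal$blank_mean, blank_area = cal$blank_mean,
                        dilution = 1, mass_g = 0.1, volume_ml = 4)
  q <- quantify_aas(rec, list(Cd = cal))
  expect_true(q$below_lod)
  expect_equal(q$tissue_mg_per_kg, 0)
  expect_error(quantify_aas(rec, list()), "no calibration")
  expect_error(quantify_aas(rec[, -3], list(Cd = cal)), "missing column")
})
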