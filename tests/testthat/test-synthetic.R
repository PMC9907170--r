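test_that("Gompertz curve realizes the trait geometry exactly", {
  spec <- well_sim_spec(0.05, 300, 0.012, 3)
  # asymptote
  expect_equal(gompertz_log_ratio(spec, 1e7), 3, tolerance = 1e-9)
  # closed form at t = lambda
  expect_equal(gompertz_log_ratio(spec, 300), 3 * exp(-exp(1)))
  # tangent at the inflection has slope mu and crosses L = 0 at lambda
  h <- 1e-4
  t_infl <- 300 + 3 / (0.012 * exp(1))  # where the inner exponent is 0
  s <- (gompertz_log_ratio(spec, t_infl + h) -
          gompertz_log_ratio(spec, t_infl - h)) / (2 * h)
  expect_equal(s, 0.012, tolerance = 1e-6)
  L_infl <- gompertz_log_ratio(spec, t_infl)
  expect_equal(t_infl - L_infl / s, 300, tolerance = 1e-3)
})

test_that("treatment models modify traits as specified", {
  spec <- well_sim_spec(0.05, 300, 0.012, 3)
  tox <- treatment_model("toxic", on_lambda = c(1, 1, 2),
                         on_mu = c(0.5, 1, 2), on_kappa = c(0.4, 1, 2))
  expect_equal(apply_treatment(spec, tox, 0), spec)  # identity at zero dose
  at_ec50 <- apply_treatment(spec, tox, 1)
  expect_equal(at_ec50$mu, 0.012 * 0.75)  # half-maximal Hill at ec50
  expect_equal(at_ec50$lambda, 300 * 1.5)
  expect_equal(at_ec50$A, 3 * 0.8)

  ft <- treatment_model("freeze_thaw", survivorship = 0.01)
  after2 <- apply_treatment(spec, ft, 2)
  expect_equal(after2$od_init, 0.05 * 0.01^2)
  expect_equal(after2$mu, spec$mu)  # traits untouched

  lethal <- treatment_model("toxic", on_mu = c(1.5, 1, 2))
  expect_error(apply_treatment(spec, lethal, 100), "non-positive")
})

test_that("freeze-thaw lag extension matches the analytic inoculum delay", {
  # Reducing the starting population by s^n delays detection-referenced
  # growth by ln(1/s^n)/mu: the culture spends that long climbing back to
  # the detection floor. Both wells are analyzed with the same floor (the
  # control inoculum), mirroring a detector that cannot see below it.
  spec <- well_sim_spec(0.05, 200, 0.01, 4)
  ft <- treatment_model("freeze_thaw", survivorship = 0.5)
  treated <- apply_treatment(spec, ft, 2)
  tt <- default_time_grid(cycles = 250)
  floor_od <- spec$od_init
  cv_c <- log_transform(spec$od_init * exp(gompertz_log_ratio(spec, tt)),
                        tt, init_cycles = 1, od_floor = floor_od)
  od_tr <- treated$od_init * exp(gompertz_log_ratio(treated, tt))
  cv_t <- log_transform(od_tr, tt, init_cycles = 1, od_floor = floor_od)
  lag_c <- estimate_traits(cv_c)$lambda
  lag_t <- estimate_traits(cv_t)$lambda
  expected_delay <- log(1 / 0.5^2) / 0.01
  expect_equal(lag_t - lag_c, expected_delay, tolerance = 0.10)
})

test_that("measured plates compress true OD through the calibration inverse", {
  calib <- reference_calibration()
  quiet <- noise_spec(od_sd = 0, spike_prob = 0, blank_offset = 0)
  tt <- seq(0, 40, 10)
  plate <- measure_plate(list(A1 = rep(3.0777, 5)), tt, calib, quiet,
                         n_blanks = 1, seed = 1)
  expect_equal(plate$A1$od_raw, rep(1.0, 5), tolerance = 1e-6)

  offs <- noise_spec(od_sd = 0, spike_prob = 0, blank_offset = 0.08)
  plate2 <- measure_plate(list(A1 = rep(0, 5)), tt, calib, offs,
                          n_blanks = 2, seed = 1)
  for (w in names(plate2)) {
    expect_equal(plate2[[w]]$od_raw, rep(0.08, 5))
  }
})

test_that("simulation is deterministic given the seed", {
  p1 <- small_screen(seed = 5)
  p2 <- small_screen(seed = 5)
  expect_identical(lapply(p1$timeseries, `[[`, "od_raw"),
                   lapply(p2$timeseries, `[[`, "od_raw"))
  p3 <- small_screen(seed = 6)
  expect_false(identical(lapply(p1$timeseries, `[[`, "od_raw"),
                         lapply(p3$timeseries, `[[`, "od_raw")))

  b1 <- simulate_burst_trace(reference_burst_params()[[2]],
                             noise_sd = 0.002, seed = 3)
  b2 <- simulate_burst_trace(reference_burst_params()[[2]],
                             noise_sd = 0.002, seed = 3)
  expect_identical(b1$od650, b2$od650)
})

test_that("screen design counts wells and blanks as laid out", {
  sim <- small_screen(doses = c(0, 1), replicates = 3)
  map <- sim$map
  expect_equal(sum(map$role == "sample"), 2 * 2 * 3)
  expect_equal(sum(map$role == "blank"), 3)
  expect_length(sim$timeseries, 15)
  # every mapped well has a series
  expect_setequal(paste0(map$plate_id, ":", map$well),
                  names(sim$timeseries))
})

test_that("large designs split across plates at 93 sample wells", {
  genos <- lapply(1:8, function(i) well_sim_spec(0.05, 300, 0.012, 3))
  names(genos) <- paste0("g", 1:8)
  genos$empty <- well_sim_spec(0.05, 300, 0.012, 3)
  sim <- simulate_screen(genos, treatment_model("toxic"),
                         doses = c(0, 1, 2, 4), replicates = 3,
                         times = seq(0, 100, 10), seed = 2)
  map <- sim$map
  expect_equal(sum(map$role == "sample"), 9 * 4 * 3)
  expect_gte(length(unique(map$plate_id)), 2)
  counts <- table(map$plate_id[map$role == "sample"])
  expect_true(all(counts <= 93))
})

test_that("dilution series round-trips the generating calibration", {
  calib <- reference_calibration()
  factors <- c(1, 2, 4, 8, 16, 32, 64, 128, 256, 400)
  pts <- simulate_dilution_series(calib, anchor_true = 0.01,
                                  factors = factors)
  pairs <- true_od_from_dilution(
    data.frame(dilution_factor = factors, od_recorded = pts$od_recorded),
    anchor_true_od = 0.01)
  fit <- fit_calibration(pairs)
  expect_equal(fit$coefficients, calib$coefficients, tolerance = 1e-4)
  expect_error(simulate_dilution_series(calib, 0.05, c(0, 1)), "positive")
})
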