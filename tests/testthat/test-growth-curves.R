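test_that("smoothing preserves constants and linear ramps, removes spikes", {
  expect_equal(smooth_series(rep(0.3, 20)), rep(0.3, 20))
  expect_equal(smooth_series(c(0.1, 0.1, 0.9, 0.1, 0.1), 3, 1),
               rep(0.1, 5))
  ramp <- seq(0.1, 2, length.out = 50)
  sm <- smooth_series(ramp)
  expect_equal(sm[3:48], ramp[3:48], tolerance = 1e-12)
  expect_error(smooth_series(1:10, despike_window = 4), "odd")
  expect_error(smooth_series(1:3, avg_window = 5), "larger")
})

test_that("log transform uses the initial-cycle mean and clamps at the floor", {
  cv <- log_transform(c(0.1, 0.2, 0.4), c(0, 10, 20), init_cycles = 1)
  expect_equal(cv$log_ratio, c(0, log(2), log(4)))
  cv2 <- log_transform(rep(0.1, 5), seq(0, 40, 10), init_cycles = 1)
  expect_equal(cv2$log_ratio, rep(0, 5))
  cv3 <- log_transform(c(0.09, 0.10, 0.11, 0.2), c(0, 10, 20, 30),
                       init_cycles = 3)
  expect_equal(cv3$od_init, 0.10)
  # all-zero series: degenerate flag, L identically 0
  cv4 <- log_transform(rep(0, 5), seq(0, 40, 10), init_cycles = 1)
  expect_true("degenerate_curve" %in% cv4$flags)
  expect_equal(cv4$log_ratio, rep(0, 5))
})

test_that("traits recover a pure exponential and a flat curve exactly", {
  tt <- seq(0, 500, by = 10)
  cv <- log_transform(0.05 * exp(0.01 * tt), tt, init_cycles = 1)
  tr <- estimate_traits(cv)
  expect_equal(tr$mu, 0.01, tolerance = 1e-10)
  expect_equal(tr$lambda, 0, tolerance = 1e-7)

  flat <- log_transform(rep(0.1, 11), seq(0, 100, 10), init_cycles = 1)
  trf <- estimate_traits(flat)
  expect_equal(trf$mu, 0)
  expect_equal(trf$lambda, 0)
  expect_equal(trf$kappa, 0.1)
})

test_that("traits recover Gompertz parameters across the simulator grid", {
  # Sampling is scaled to the exponential-phase duration A/mu so the slope
  # window resolves the steepest curves. The observable tangent lag of the
  # generator is lambda + L(0)/mu exactly: normalizing to the observed
  # initial OD subtracts the (usually negligible) Gompertz tail at t = 0.
  for (lam in c(60, 300, 600)) for (mu in c(0.003, 0.012, 0.03))
    for (A in c(1, 2.5, 4)) {
      spec <- well_sim_spec(0.05, lam, mu, A)
      dt <- max(1, min(10, round((A / mu) / 30)))
      tt <- seq(0, lam + 6 * A / mu, by = dt)
      cv <- log_transform(0.05 * exp(gompertz_log_ratio(spec, tt)), tt,
                          init_cycles = 1)
      tr <- estimate_traits(cv)
      lam_obs <- lam + gompertz_log_ratio(spec, 0) / mu
      expect_equal(tr$mu, mu, tolerance = 0.02)
      expect_equal(tr$lambda, lam_obs, tolerance = 0.05)
      expect_equal(tr$kappa, 0.05 * exp(A), tolerance = 0.02)
    }
})

test_that("replicate aggregation averages pointwise with correct SEM", {
  tt <- seq(0, 100, 10)
  c1 <- log_transform(0.05 * exp(0.01 * tt), tt, init_cycles = 1)
  agg1 <- aggregate_replicates(list(c1, c1))
  expect_equal(agg1$mean$log_ratio, c1$log_ratio)
  expect_equal(agg1$sem, rep(0, length(tt)))

  c2 <- c1; c2$log_ratio <- c1$log_ratio + 2
  agg2 <- aggregate_replicates(list(c1, c2))
  expect_equal(agg2$mean$log_ratio, c1$log_ratio + 1)
  expect_equal(agg2$sem, rep(1, length(tt)))  # sd = sqrt(2), n = 2

  agg3 <- aggregate_replicates(list(c1))
  expect_equal(agg3$sem, rep(0, length(tt)))
  bad <- log_transform(c(0.05, 0.06), c(0, 10), init_cycles = 1)
  expect_error(aggregate_replicates(list(c1, bad)), "shared time grid")
})

test_that("Phi on a noiseless logistic lands where the rate is 5% of maximum", {
  cv <- logistic_curve()
  tr <- estimate_traits(cv)
  ph <- find_phi(cv, tr)
  expect_true(ph$reached)
  # instantaneous per-capita rate at Phi (analytic for the logistic)
  r <- 0.01; K <- 5; N0 <- 0.05
  Nphi <- K / (1 + (K / N0 - 1) * exp(-r * ph$phi))
  expect_lte(r * (1 - Nphi / K) / tr$mu, 0.05)
  # density at Phi: 94-96.5% of carrying capacity
  expect_gte(Nphi / K, 0.94)
  expect_lte(Nphi / K, 0.965)
})

test_that("Phi shifting is additive and capped at the grid end", {
  cv <- logistic_curve()
  tr <- estimate_traits(cv)
  ph0 <- find_phi(cv, tr)
  ph1 <- find_phi(cv, tr, shift = 1000)
  expect_equal(ph1$phi, min(ph0$phi + 1000, max(cv$times)))
  phbig <- find_phi(cv, tr, shift = 1e6)
  expect_equal(phbig$phi, max(cv$times))
  expect_error(find_phi(cv, tr, threshold_fraction = 1.5), "threshold")
  flat <- log_transform(rep(0.1, 11), seq(0, 100, 10), init_cycles = 1)
  expect_error(find_phi(flat, estimate_traits(flat)), "non-growing")
})

test_that("Phi is flagged unreached on a culture still in exponential phase", {
  tt <- seq(0, 500, 10)
  cv <- log_transform(0.05 * exp(0.01 * tt), tt, init_cycles = 1)
  tr <- estimate_traits(cv)
  expect_warning(ph <- find_phi(cv, tr), "never fell")
  expect_false(ph$reached)
  expect_equal(ph$phi, 500)
})

test_that("AUC integrates rectangles, triangles and clips negative dips", {
  tt <- seq(0, 100, 10)
  const <- log_transform(rep(0.1 * exp(2), 11), tt, init_cycles = 1)
  const$log_ratio <- rep(2, 11)  # L == 2 exactly
  expect_equal(compute_auc(const, 100)$auc, 200)
  expect_equal(compute_auc(const, 55)$auc, 110)  # partial interval

  lin <- const; lin$log_ratio <- 0.02 * tt
  expect_equal(compute_auc(lin, 100)$auc, 0.02 * 100^2 / 2, tolerance = 1e-9)

  dip <- const; dip$log_ratio <- c(-0.1, rep(2, 10))
  a_clip <- compute_auc(dip, 100, clip_negative = TRUE)$auc
  a_raw <- compute_auc(dip, 100, clip_negative = FALSE)$auc
  expect_gt(a_clip, a_raw)
  expect_equal(a_clip, 10 * (0 + 2) / 2 + 90 * 2)

  over <- compute_auc(const, 1e5)
  expect_true("phi_beyond_grid" %in% over$flags)
  expect_equal(over$phi_used, 100)
})

test_that("AUC is non-decreasing in Phi and delta AUC behaves at the bounds", {
  cv <- logistic_curve()
  phis <- seq(100, 2500, by = 100)
  aucs <- vapply(phis, function(p) compute_auc(cv, p)$auc, 0)
  expect_true(all(diff(aucs) >= 0))

  a1 <- compute_auc(cv, 800)
  expect_equal(relative_auc(a1, a1), 1.0)
  zero <- log_transform(rep(0.05, length(cv$times)), cv$times,
                        init_cycles = 1)
  a0 <- compute_auc(zero, 800)
  expect_equal(relative_auc(a0, a1), 0.0)
  expect_error(relative_auc(a1, a0), "near.*zero|zero")
  a2 <- compute_auc(cv, 900)
  expect_error(relative_auc(a1, a2), "different Phi")
})

test_that("dominated curves give delta AUC at most 1", {
  cv <- logistic_curve()
  worse <- cv
  worse$log_ratio <- cv$log_ratio * 0.7
  ph <- 800
  expect_lte(relative_auc(compute_auc(worse, ph), compute_auc(cv, ph)), 1)
})
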