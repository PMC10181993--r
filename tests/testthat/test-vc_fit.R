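test_that("PLC is computed relative to the first-pressure reference", {
  plc <- compute_plc(data.frame(psi_mpa = c(-0.8, -1.3), k = c(2, 2)))$plc
  expect_equal(plc, c(0, 0))

  plc <- compute_plc(data.frame(psi_mpa = c(-0.8, -2, -4),
                                k = c(2, 1, 0)))$plc
  expect_equal(plc, c(0, 50, 100))

  # noisy reading above the reference gives negative PLC, kept and flagged
  out <- compute_plc(data.frame(psi_mpa = c(-0.8, -1.3), k = c(2, 2.2)))
  expect_equal(out$plc, c(0, -10))
  expect_equal(attr(out, "qc_negative"), 1)

  expect_error(compute_plc(data.frame(psi_mpa = c(-0.8, -1.3), k = c(0, 1))),
               "unusable")
  expect_error(compute_plc(data.frame(psi_mpa = c(-1.3, -0.8), k = c(2, 1))),
               "decreasing")
})

test_that("PLC is invariant to rescaling of conductivity units", {
  sw <- data.frame(psi_mpa = default_pressures(),
                   k = c(2, 1.9, 1.7, 1.3, 0.9, 0.5, 0.3, 0.15, 0.1, 0.05))
  sw2 <- transform(sw, k = k * 3600)  # kg/s -> kg/h
  expect_equal(compute_plc(sw)$plc, compute_plc(sw2)$plc)
  expect_equal(fit_pammenter(compute_plc(sw))$psi50,
               fit_pammenter(compute_plc(sw2))$psi50, tolerance = 1e-9)
})

test_that("sigmoid fit recovers noiseless parameters to solver tolerance", {
  psi <- default_pressures()
  cases <- list(c(-2.5, 50), c(-1.8, 30), c(-3.4, 120), c(-4.0, 80))
  for (cs in cases) {
    fit <- fit_pammenter(data.frame(psi_mpa = psi,
                                    plc = pammenter_plc(psi, cs[1], cs[2])))
    expect_true(fit$converged)
    expect_equal(fit$psi50, cs[1], tolerance = 1e-6)
    expect_equal(fit$slope, cs[2], tolerance = 1e-5)
    # the fitted sigmoid passes through 50% at its own psi50
    expect_equal(pammenter_plc(fit$psi50, fit$psi50, fit$slope), 50)
  }
})

test_that("fit SSE never exceeds a dense grid-search oracle", {
  set.seed(101)
  psi <- default_pressures()
  for (i in 1:10) {
    truth <- c(runif(1, -4.5, -1.5), runif(1, 30, 150))
    plc <- pammenter_plc(psi, truth[1], truth[2]) + rnorm(length(psi), 0, 4)
    fit <- fit_pammenter(data.frame(psi_mpa = psi, plc = plc))
    expect_lte(fit$sse, grid_search_sse(psi, plc) + 1e-9)
  }
})

test_that("degenerate curves are refused rather than fitted", {
  psi <- default_pressures()
  expect_error(fit_pammenter(data.frame(psi_mpa = psi[1:3],
                                        plc = c(0, 40, 80))),
               "fewer than")
  expect_error(fit_pammenter(data.frame(psi_mpa = psi,
                                        plc = rep(5, length(psi)) +
                                          seq(0, 9))),
               "span")
})

test_that("thresholds follow the 50/S offsets and bracket psi50", {
  thr <- derive_thresholds(-2.0, 50)
  expect_equal(thr$psi12, -1.0)
  expect_equal(thr$psi88, -3.0)
  thr <- derive_thresholds(-3.0, 25)
  expect_equal(thr$psi12, -1.0)
  expect_equal(thr$psi88, -5.0)
  expect_error(derive_thresholds(-2, 0), "positive")

  # the sigmoid at the derived thresholds: 100/(1+e^2) and 100/(1+e^-2)
  expect_equal(pammenter_plc(thr$psi12, -3.0, 25), 100 / (1 + exp(2)))
  expect_equal(pammenter_plc(thr$psi88, -3.0, 25), 100 / (1 + exp(-2)))
  expect_true(thr$psi88 < -3.0 && -3.0 < thr$psi12)
})

test_that("model PLC increases monotonically as pressure decreases", {
  set.seed(7)
  for (i in 1:20) {
    psi50 <- runif(1, -5, -1); s <- runif(1, 10, 200)
    psi <- seq(-0.1, -8, length.out = 50)
    plc <- pammenter_plc(psi, psi50, s)
    expect_true(all(diff(plc) >= 0))  # flat only where the tails underflow
    mid <- abs(psi - psi50) < 2
    expect_true(all(diff(plc[mid]) > 0))
  }
})

test_that("variety aggregation reports means and standard errors", {
  fits <- data.frame(variety = "A", season = "summer", organ = "stem",
                     psi12 = c(-1, -1.4, -1.2), psi50 = c(-2, -2.4, -2.2),
                     psi88 = c(-3, -3.4, -3.2), slope = c(40, 50, 60),
                     converged = TRUE)
  s <- aggregate_variety(fits)
  expect_equal(s$n_plants, 3)
  expect_equal(s$psi50_mean, -2.2)                 # hand: (-2-2.4-2.2)/3
  expect_equal(s$psi50_se, 0.2 / sqrt(3))          # sd 0.2, n 3
  expect_equal(s$slope_mean, 50)

  one <- aggregate_variety(fits[1, ])
  expect_equal(one$psi50_mean, -2)
  expect_true(is.na(one$psi50_se))

  two <- aggregate_variety(fits[c(1, 1), ])        # identical fits
  expect_equal(two$psi50_se, 0)
})

test_that("group comparison matches the pooled-variance t formula", {
  ga <- data.frame(psi50 = c(1, 2, 3))
  gb <- data.frame(psi50 = c(2, 4, 6))
  res <- compare_groups(ga, gb)
  expect_equal(res$delta, 2)
  # hand: sp2 = (2*1 + 2*4)/4 = 2.5; t = 2/sqrt(2.5*(2/3))
  expect_equal(res$t, 2 / sqrt(2.5 * (2 / 3)))
  expect_equal(res$df, 4)

  same <- compare_groups(ga, ga)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  const <- compare_groups(data.frame(psi50 = c(1, 1)),
                          data.frame(psi50 = c(2, 2)))
  expect_true(const$degenerate)
  expect_error(compare_groups(data.frame(psi50 = 1), gb), "at least 2")
})

test_that("hydraulic vulnerability segmentation is leaf minus stem", {
  leaf <- data.frame(variety = "CS", season = "summer",
                     leaf_position = "basal",
                     psi12_mean = -1.0, psi50_mean = -1.8)
  stem <- data.frame(variety = "CS", season = "summer",
                     psi12_mean = -1.9, psi50_mean = -2.6)
  hvs <- compute_hvs(leaf, stem)
  expect_equal(hvs$hvs_psi50, 0.8)
  expect_equal(hvs$hvs_psi12, 0.9)
  expect_equal(compute_hvs(stem, stem)$hvs_psi50, 0)
  stem_other <- transform(stem, season = "spring")
  expect_error(compute_hvs(leaf, stem_other), "match")
})

test_that("paper-scale organ means give segmentation in a plausible band", {
  # leaf thresholds less negative than stem by roughly one MPa, as observed
  # in grapevine: segmentation should land between 0.5 and 1.1 MPa
  leaf <- data.frame(variety = "CS", season = "summer",
                     psi12_mean = -1.1, psi50_mean = -1.8)
  stem <- data.frame(variety = "CS", season = "summer",
                     psi12_mean = -1.9, psi50_mean = -2.6)
  hvs <- compute_hvs(leaf, stem)
  expect_gt(hvs$hvs_psi50, 0.5)
  expect_lt(hvs$hvs_psi50, 1.1)
})
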