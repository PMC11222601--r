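test_that("param_config validates its fields", {
  expect_error(param_config(threshold_fraction = 0), "in \\(0, 1\\)")
  expect_error(param_config(window = c(3, 1)), "t_start < t_end")
  expect_equal(param_config()$threshold_fraction, 0.15)
})

test_that("arrival time follows the 15%-of-range rule", {
  r <- compute_toa(c(0, 0, 0, 50, 100, 100), fps = 6)
  expect_true(r$valid)
  expect_equal(r$toa, 0.5)  # frame 3: first above 0 + 0.15 * 100
  expect_false(compute_toa(rep(4, 10), fps = 6)$valid)
})

test_that("transit time spans the rise and fall triggers", {
  y <- c(0, 0, 30, 100, 100, 100, 60, 10, 0, 0)
  r <- compute_transit(y, fps = 6)
  expect_true(r$valid)
  # baseline mean([0,0,30]) = 10 -> rise frame 2 (30 > 23.5),
  # fall frame 6 (60 < 100 - 0.15*90 = 86.5): transit = 4/6 s
  expect_equal(r$transit, 4 / 6)
  expect_gte(r$transit, 0)
  # monotone series has no washout
  expect_false(compute_transit(c(0, 0, 10, 40, 80, 100), fps = 6)$valid)
  # baseline-shift invariance
  r2 <- compute_transit(y + 250, fps = 6)
  expect_equal(r2$transit, r$transit)
})

test_that("time to peak takes the earliest maximal frame", {
  r <- compute_ttp(c(0, 10, 80, 80, 20), fps = 6)
  expect_true(r$valid)
  expect_equal(r$ttp, 2 / 6)
  expect_false(compute_ttp(rep(1, 8), fps = 6)$valid)
})

test_that("AUC matches dense quadrature of the fitted curve", {
  y <- model_series(0, 80, 0.1, 8, 2.0)
  fit <- fit_tic(y, 6)
  r <- compute_auc(fit)
  expect_true(r$valid)
  # oracle: 1000-subinterval quadrature of the same model
  tt <- seq(0, 59 / 6, length.out = 1001)
  enh <- pmax(bolus_model(tt, fit = fit) - coef(fit)[["a0"]], 0)
  dense <- sum(diff(tt) * (head(enh, -1) + tail(enh, -1)) / 2)
  expect_equal(r$auc, dense, tolerance = 0.02)
  expect_gte(r$auc, 0)
})

test_that("AUC of a flat fit is zero and a rectangle integrates exactly", {
  flat <- structure(list(coefficients = c(a0 = 5, a1 = 0, a2 = 0, a3 = 1,
                                          t0 = 1),
                         rss = 0, converged = TRUE,
                         series = rep(5, 31), fps = 6,
                         times = (0:30) / 6),
                    class = "tic_fit")
  expect_equal(compute_auc(flat)$auc, 0)
  # constant enhancement of 10 over a 2 s window: area 20
  rect <- flat
  rect$coefficients <- c(a0 = 0, a1 = 10, a2 = 0, a3 = 1e6, t0 = -1)
  r <- compute_auc(rect, param_config(window = c(1, 3)))
  expect_equal(r$auc, 20, tolerance = 1e-6)
})

test_that("inflow rate matches the analytic derivative maximum", {
  y <- model_series(0, 100, 0.08, 6, 2.5)
  fit <- fit_tic(y, 6)
  r <- compute_flow(fit)
  expect_true(r$valid)
  p <- coef(fit)
  tt <- seq(0, 59 / 6, length.out = 20000)
  oracle_max <- max(oracle_bolus_deriv(tt, p[["a1"]], p[["a2"]], p[["a3"]],
                                       p[["t0"]]))
  expect_equal(r$flow, oracle_max, tolerance = 0.01)
  expect_gte(r$flow, 0)
})

test_that("inflow rate grows with the rise slope and vanishes without inflow", {
  mk <- function(a1, a3) structure(
    list(coefficients = c(a0 = 0, a1 = a1, a2 = 0.1, a3 = a3, t0 = 3),
         rss = 0, converged = TRUE, series = rep(0, 61), fps = 6,
         times = (0:60) / 6),
    class = "tic_fit")
  flows <- vapply(c(1, 5, 25), function(a3) compute_flow(mk(80, a3))$flow,
                  numeric(1))
  expect_true(all(diff(flows) > 0))
  expect_equal(compute_flow(mk(0, 5))$flow, 0)
  nc <- mk(80, 5); nc$converged <- FALSE
  expect_false(compute_flow(nc)$valid)
  expect_false(compute_auc(nc)$valid)
})

test_that("parameter maps respect the mask, validity and ordering invariants", {
  ph <- cached_phantom(noise_sigma = 0)
  sm <- gaussian_lowpass(ph$sequence, 1)
  mask <- segment_vessels(ph$sequence)
  toa <- build_param_map(sm, mask, "TOA")
  ttp <- build_param_map(sm, mask, "TTP")
  transit <- build_param_map(sm, mask, "TRANSIT")
  # validity never leaves the mask; values finite where valid
  for (m in list(toa, ttp, transit)) {
    expect_true(all(m$valid <= mask$mask))
    expect_true(all(is.finite(m$values[m$valid])))
  }
  both <- toa$valid & ttp$valid
  expect_true(all(toa$values[both] <= ttp$values[both]))
  expect_true(all(transit$values[transit$valid] >= 0))
  expect_true(all(toa$valid[transit$valid]))
})

test_that("all five map kinds are shift-invariant under a uniform offset", {
  ph <- cached_phantom(noise_sigma = 0)
  sm <- gaussian_lowpass(ph$sequence, 1)
  mask <- segment_vessels(ph$sequence)
  shifted <- sm; shifted$frames <- shifted$frames + 77
  for (kind in c("TOA", "TTP", "TRANSIT", "AUC", "FLOW")) {
    m1 <- build_param_map(sm, mask, kind)
    m2 <- build_param_map(shifted, mask, kind)
    expect_identical(m1$valid, m2$valid)
    expect_equal(m1$values[m1$valid], m2$values[m2$valid], tolerance = 1e-6)
  }
})

test_that("arrival time is monotone along the tube and late inside the leak", {
  ph <- cached_phantom(noise_sigma = 0)
  sm <- gaussian_lowpass(ph$sequence, 1)
  toa <- build_param_map(sm, ph$vessel_mask | ph$leak_mask, "TOA")
  # monotone front propagation: binned by true arrival, estimated arrival
  # medians must be nondecreasing along the tube
  sel <- ph$vessel_mask & !ph$leak_mask & toa$valid
  tru <- ph$toa_true[sel]; est <- toa$values[sel]
  bins <- cut(tru, breaks = stats::quantile(tru, 0:6 / 6), include.lowest = TRUE)
  med <- tapply(est, bins, stats::median)
  expect_true(all(diff(med) >= 0))
  # breakpoint blob arrives later than its upstream vessel segment
  upstream <- ph$vessel_mask & !ph$leak_mask &
    ph$toa_true <= stats::quantile(ph$toa_true[ph$vessel_mask], 0.25)
  expect_gt(stats::median(toa$values[ph$leak_mask & toa$valid]),
            stats::median(toa$values[upstream & toa$valid]))
})

test_that("degenerate sequences produce an empty-map error", {
  static <- dsa_sequence(array(2, c(8, 12, 12)), fps = 6)
  mask <- matrix(TRUE, 12, 12)
  expect_error(build_param_map(static, mask, "TOA"), "empty parameter map")
  expect_error(build_param_map(static, matrix(TRUE, 5, 5), "TOA"),
               "mask size")
})
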