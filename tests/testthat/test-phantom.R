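test_that("phantom specs validate geometry and rates", {
  expect_error(phantom_spec(n_frames = 4), ">= 6")
  expect_error(phantom_spec(front_speed = 0), "positive")
  expect_error(phantom_spec(tube_path = cbind(c(-5, 10), c(10, 10))),
               "leaves the image bounds")
  expect_error(phantom_spec(breakpoint = list(position_frac = 0.5,
                                              leak_radius_px = 5,
                                              leak_fill_rate = 1,
                                              leak_clear_rate = 0.5,
                                              spread_speed = 4),
                            washout_rate = 0.25),
               "clears slower")
})

test_that("generation is deterministic and leaves the caller RNG alone", {
  a <- generate_phantom(small_spec(seed = 9))
  set.seed(123); before <- runif(3)
  b <- generate_phantom(small_spec(seed = 9))
  expect_identical(a$sequence$frames, b$sequence$frames)
  set.seed(123)
  expect_identical(before, runif(3))  # generator restored the RNG state
  c_ <- generate_phantom(small_spec(seed = 10))
  expect_false(identical(a$sequence$frames, c_$sequence$frames))
})

test_that("noiseless vessel profiles rise to a single peak then decay", {
  ph <- cached_phantom(noise_sigma = 0, breakpoint = FALSE)
  px <- which(ph$vessel_mask, arr.ind = TRUE)
  set.seed(1)
  for (i in sample(nrow(px), 25)) {
    y <- ph$sequence$frames[, px[i, 1], px[i, 2]]
    k <- which.max(y)
    expect_true(all(diff(y[seq_len(k)]) >= -1e-9))
    if (k < length(y)) expect_true(all(diff(y[k:length(y)]) <= 1e-9))
  }
})

test_that("ground-truth arrival equals arc distance over front speed", {
  ph <- cached_phantom(noise_sigma = 0, breakpoint = FALSE)
  sp <- ph$spec
  # farthest tube pixels arrive at path_length / front_speed (up to the
  # half-pixel arc resampling of the centerline)
  d <- sqrt(rowSums(diff(sp$tube_path)^2))
  expect_equal(max(ph$toa_true[ph$vessel_mask]), sum(d) / sp$front_speed,
               tolerance = 0.51 / sp$front_speed)
  expect_equal(min(ph$toa_true[ph$vessel_mask]), 0, tolerance = 1e-9)
  # finite exactly on the truth masks; nondecreasing along the path
  expect_identical(is.finite(ph$toa_true), ph$vessel_mask | ph$leak_mask)
})

test_that("extravasated contrast persists into the late frames", {
  ph <- cached_phantom(noise_sigma = 0)
  nt <- dim(ph$sequence$frames)[1]
  late <- apply(ph$sequence$frames[(nt - ceiling(0.1 * nt) + 1):nt, , ,
                                   drop = FALSE], c(2, 3), mean)
  expect_gt(mean(late[ph$leak_mask]),
            mean(late[ph$vessel_mask & !ph$leak_mask]))
})

test_that("experiment batteries honor composition, labels and determinism", {
  bat <- make_experiment_battery(n_cases = 6, breakpoint_fraction = 0.5,
                                 seed = 4, height = 48, width = 48,
                                 n_frames = 24)
  expect_length(bat$cases, 6)
  expect_equal(sum(bat$labels$has_breakpoint), 3)
  has_leak <- vapply(bat$cases, function(p) any(p$leak_mask), logical(1))
  expect_identical(has_leak, bat$labels$has_breakpoint)
  bat2 <- make_experiment_battery(n_cases = 6, breakpoint_fraction = 0.5,
                                  seed = 4, height = 48, width = 48,
                                  n_frames = 24)
  expect_identical(bat$cases[[1]]$sequence$frames,
                   bat2$cases[[1]]$sequence$frames)
  none <- make_experiment_battery(n_cases = 3, breakpoint_fraction = 0,
                                  seed = 1, height = 48, width = 48,
                                  n_frames = 24)
  expect_false(any(vapply(none$cases, function(p) any(p$leak_mask),
                          logical(1))))
})

test_that("end-to-end arrival recovery stays within one frame period", {
  ph <- cached_phantom(noise_sigma = 0)
  sm <- gaussian_lowpass(ph$sequence, 1)
  mask <- segment_vessels(ph$sequence)
  toa <- build_param_map(sm, mask, "TOA")
  vess <- ph$vessel_mask
  err <- abs(toa$values - ph$toa_true)
  ok <- vess & toa$valid & err <= 1 / ph$spec$fps + 1e-9
  expect_gte(sum(ok) / sum(vess), 0.95)
  # default noise: median error within one frame period
  phn <- cached_phantom(noise_sigma = 2)
  smn <- gaussian_lowpass(phn$sequence, 1)
  toan <- build_param_map(smn, segment_vessels(phn$sequence), "TOA")
  sel <- phn$vessel_mask & toan$valid
  expect_lte(stats::median(abs(toan$values - phn$toa_true)[sel]),
             1 / phn$spec$fps)
})
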