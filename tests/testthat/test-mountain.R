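tp <- transform_params()

test_that("single-integrator reward intensity has the half-max property", {
  expect_equal(reward_intensity_single(120, 120, 3.7), 0.5)
  expect_identical(reward_intensity_single(0, 100, 2), 0)
  expect_equal(reward_intensity_single(200, 100, 2), 0.8)
  ff <- seq(0, 500, length.out = 100)
  u <- reward_intensity_single(ff, 150, 4)
  expect_true(all(diff(u) >= 0) && all(u >= 0 & u <= 1))
  # log-space evaluation survives exponents that overflow the direct form
  expect_equal(reward_intensity_single(1000, 10, 200), 1)
  expect_equal(reward_intensity_single(10, 1000, 200), 0)
})

test_that("extended surface matches a naive term-by-term transcription", {
  prm <- study_truth_params()
  f <- exp(seq(log(5), log(600), length.out = 15))
  p <- exp(seq(log(0.5), log(60), length.out = 15))
  grid <- expand.grid(f = f, p = p)
  for (j in 1:2) {
    d <- prm$durations[j]
    got <- time_allocation_extended(grid$f, grid$p, d, prm, tp)
    want <- naive_time_allocation_extended(grid$f, grid$p, prm$a, prm$g,
                                           prm$ta_min, prm$ta_max[j],
                                           prm$f_hm[j], prm$p_e[j])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("time allocation sits halfway at matched price and saturated reward", {
  # intensity pinned at ceiling via a tiny f_hm, price at the half-fall point
  prm <- single_mountain_params(a = 4, g = 6, ta_min = 0.08, durations = 1,
                                f_hm = 0.5, p_e = 10, ta_max = 0.92)
  ta <- time_allocation_extended(ff_params()$f_near_max, 10, 1, prm, tp)
  expect_equal(ta, (0.92 + 0.08) / 2, tolerance = 1e-6)
  # zero pulse frequency floors the surface
  expect_equal(time_allocation_extended(0, 10, 1, prm, tp), prm$ta_min)
})

test_that("original surface is the extended surface with identity transforms", {
  prm <- study_truth_params()
  expect_equal(time_allocation_original(0, 5, 1, prm), prm$ta_min)
  # far below both transform bends, extended and original nearly coincide
  small <- single_mountain_params(a = 3, g = 4, ta_min = 0.1, durations = 1,
                                  f_hm = 40, p_e = 20, ta_max = 0.9)
  f <- seq(20, 80, length.out = 10)
  expect_equal(time_allocation_original(f, 20, 1, small),
               time_allocation_extended(f, 20, 1, small, tp),
               tolerance = 0.02)
  # as price -> 0 at f = f_hm the original surface tends to its ceiling
  expect_equal(time_allocation_original(40, 1e-9, 1, small), small$ta_max[1],
               tolerance = 1e-6)
})

test_that("surfaces are bounded and monotone in frequency and price", {
  set.seed(21)
  for (i in 1:20) {
    prm <- single_mountain_params(
      a = runif(1, 0.5, 8), g = runif(1, 0.5, 8),
      ta_min = runif(1, 0, 0.3), durations = 1,
      f_hm = runif(1, 30, 400), p_e = runif(1, 1, 40),
      ta_max = runif(1, 0.5, 1))
    f <- sort(runif(30, 1, 600))
    p <- sort(runif(30, 0.2, 80))
    ta_f <- time_allocation_extended(f, 5, 1, prm, tp)
    ta_p <- time_allocation_extended(250, p, 1, prm, tp)
    expect_true(all(ta_f >= prm$ta_min - 1e-12 & ta_f <= prm$ta_max + 1e-12))
    expect_true(all(diff(ta_f) >= -1e-12))   # non-decreasing in frequency
    expect_true(all(diff(ta_p) <= 1e-12))    # non-increasing in price
  }
})

test_that("strength-duration consistency fixes the f_hm ratio across durations", {
  # FFhm(0.25)/FFhm(1) = (1 + 4C)/(1 + C) for any chronaxie C
  set.seed(31)
  for (i in 1:20) {
    prm <- sd_params(runif(1, 10, 300), runif(1, 0.05, 6))
    r <- half_max_firing_at_duration(0.25, prm) /
      half_max_firing_at_duration(1, prm)
    expect_equal(r, (1 + 4 * prm$chronaxie) / (1 + prm$chronaxie),
                 tolerance = 1e-12)
  }
})

test_that("dual surface reduces to the extended single surface at w = 1", {
  int1 <- sd_params(50, 0.15)
  int2 <- sd_params(40, 5)
  # single equivalent: f_hm mapping back through frequency following
  ffhm <- half_max_firing_at_duration(c(0.25, 1), int1)
  f_hm <- pulse_frequency_for_firing(ffhm)$pulse_frequency
  sm <- single_mountain_params(a = 3, g = 4, ta_min = 0.1,
                               durations = c(0.25, 1), f_hm = f_hm,
                               p_e = c(8, 8), ta_max = c(0.9, 0.85))
  dm <- dual_mountain_params(int1, int2, w = 1,
                             price_scale = subjective_price(8),
                             a = 3, g = 4, ta_min = 0.1,
                             durations = c(0.25, 1), ta_max = c(0.9, 0.85))
  f <- exp(seq(log(5), log(600), length.out = 50))
  p <- exp(seq(log(0.5), log(60), length.out = 50))
  grid <- expand.grid(f = f, p = p)
  for (d in c(0.25, 1)) {
    expect_equal(time_allocation_dual(grid$f, grid$p, d, dm, tp),
                 time_allocation_extended(grid$f, grid$p, d, sm, tp),
                 tolerance = 1e-9)
  }
  # degenerate weight identity at the intensity stage too
  ff <- seq(0, 400, length.out = 50)
  expect_equal(reward_intensity_dual(ff, 0.25, dm),
               reward_intensity_single(ff, ffhm[1], 4), tolerance = 1e-12)
})

test_that("integrator dropout caps achievable intensity near the weight", {
  # integrator 2's demand at 0.25 s (40 * 21 = 840 spikes/s) is far above
  # the ~343 plateau, so only integrator 1 (w = 0.6) contributes
  dm <- dual_mountain_params(sd_params(50, 0.15), sd_params(40, 5), w = 0.6,
                             price_scale = subjective_price(8),
                             a = 3, g = 4, ta_min = 0.1,
                             durations = c(0.25, 1), ta_max = c(0.9, 0.85))
  i_short <- max_achievable_intensity(dm, 0.25, tp)
  i_long <- max_achievable_intensity(dm, 1, tp)
  expect_lt(abs(i_short - 0.6), 0.05)
  expect_gt(i_long, 0.9)
  # achievable intensity is non-decreasing in duration
  ds <- c(0.1, 0.25, 0.5, 1, 2, 5)
  im <- vapply(ds, function(d) max_achievable_intensity(dm, d, tp), numeric(1))
  expect_true(all(diff(im) > 0))
  # saturation: long duration, plateau firing, rheobases well below plateau
  dm2 <- dual_mountain_params(sd_params(30, 0.1), sd_params(40, 0.2), w = 0.5,
                              price_scale = 10, a = 3, g = 6, ta_min = 0.1,
                              durations = 10, ta_max = 0.9)
  expect_equal(max_achievable_intensity(dm2, 10, tp), 1, tolerance = 0.01)
})

test_that("dual surface shifts the halfway price leftward at the short duration", {
  dm <- dual_mountain_params(sd_params(50, 0.15), sd_params(40, 5), w = 0.6,
                             price_scale = subjective_price(8),
                             a = 3, g = 4, ta_min = 0.1,
                             durations = c(0.25, 1), ta_max = c(0.9, 0.85))
  el_short <- effective_location_params(dm, 0.25, tp)
  el_long <- effective_location_params(dm, 1, tp)
  expect_gt(el_long$p_e_effective, el_short$p_e_effective)
  expect_equal(time_allocation_dual(0, 5, 0.25, dm, tp), dm$ta_min)
})

test_that("effective location parameters recover stored values for single fits", {
  # saturating regime: plateau intensity within ~1e-7 of unity
  prm <- single_mountain_params(a = 3, g = 8, ta_min = 0.1, durations = 1,
                                f_hm = 50, p_e = 9, ta_max = 0.9)
  el <- effective_location_params(prm, 1, tp)
  expect_equal(el$f_hm_effective, 50, tolerance = 1e-6)
  expect_equal(el$p_e_effective, 9, tolerance = 1e-6)
  # w = 1 dual with the matching strength-duration law agrees
  ffhm <- frequency_following(50, tp$ff)
  dm <- dual_mountain_params(sd_params(ffhm / 2, 1), sd_params(10, 2), w = 1,
                             price_scale = subjective_price(9),
                             a = 3, g = 8, ta_min = 0.1, durations = 1,
                             ta_max = 0.9)
  el2 <- effective_location_params(dm, 1, tp)
  expect_equal(el2$f_hm_effective, el$f_hm_effective, tolerance = 1e-6)
  expect_equal(el2$p_e_effective, el$p_e_effective, tolerance = 1e-6)
})

test_that("surface grids are long-format and within bounds", {
  prm <- study_truth_params()
  g <- surface_grid(prm, tp, n = 10)
  expect_equal(nrow(g), 2 * 100)
  expect_named(g, c("train_duration_s", "pulse_frequency_pps", "price_s",
                    "time_allocation"))
  expect_true(all(g$time_allocation >= prm$ta_min &
                    g$time_allocation <= max(prm$ta_max)))
})
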