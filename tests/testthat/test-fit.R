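tp <- transform_params()

test_that("joint fit recovers a known surface from noiseless data", {
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = Inf, seed = 1)
  fit <- fit_mountain(obs, fit_spec("single", n_starts = 4), tp, seed = 1)
  est <- coef(fit)
  expect_true(fit$converged)
  for (j in 1:2) {
    d <- prm$durations[j]
    expect_equal(est[[paste0("f_hm_", d)]], prm$f_hm[j], tolerance = 0.01)
    expect_equal(est[[paste0("p_e_", d)]], prm$p_e[j], tolerance = 0.01)
    expect_equal(est[[paste0("ta_max_", d)]], prm$ta_max[j], tolerance = 0.01)
  }
  expect_equal(est[["a"]], prm$a, tolerance = 0.05)
  expect_equal(est[["g"]], prm$g, tolerance = 0.05)
  # the fitted surface honours the mountain's monotonicity invariants
  fprm <- params_from_fit(fit)
  f <- sort(runif(20, 5, 500)); p <- sort(runif(20, 0.5, 50))
  expect_true(all(diff(time_allocation_extended(f, 5, 1, fprm, tp)) >= -1e-12))
  expect_true(all(diff(time_allocation_extended(250, p, 1, fprm, tp)) <= 1e-12))
})

test_that("fits are deterministic under a fixed seed and flag degenerate data", {
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = 30, seed = 3)
  f1 <- fit_mountain(obs, fit_spec("single", n_starts = 3), tp, seed = 7)
  f2 <- fit_mountain(obs, fit_spec("single", n_starts = 3), tp, seed = 7)
  expect_identical(coef(f1), coef(f2))
  flat <- obs
  flat$time_allocation <- 0.5
  ffit <- fit_mountain(flat, fit_spec("single", n_starts = 2), tp, seed = 1)
  expect_true(ffit$degenerate)
  expect_error(fit_mountain(obs[, 1:3], fit_spec("single"), tp),
               "required columns")
})

test_that("duration-consistent f_hm ordering is recovered with the right sign", {
  # truth built from the strength-duration law: f_hm(0.25) > f_hm(1)
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = 30, seed = 11)
  fit <- fit_mountain(obs, fit_spec("single", n_starts = 4), tp, seed = 2)
  est <- coef(fit)
  expect_gt(est[["f_hm_0.25"]], est[["f_hm_1"]])
})

test_that("dual fits honour the chronaxie cap and fixed-parameter assignments", {
  dm <- dual_mountain_params(sd_params(50, 0.15), sd_params(40, 5), w = 0.6,
                             price_scale = subjective_price(8),
                             a = 3, g = 4, ta_min = 0.1,
                             durations = c(0.25, 1), ta_max = c(0.9, 0.85))
  el_s <- effective_location_params(dm, 0.25, tp)
  el_l <- effective_location_params(dm, 1, tp)
  sw <- c(build_pseudo_sweeps(list(f_hm = el_s$f_hm_effective,
                                   p_e = el_s$p_e_effective), 0.25, tp = tp),
          build_pseudo_sweeps(list(f_hm = el_l$f_hm_effective,
                                   p_e = el_l$p_e_effective), 1, tp = tp))
  sched <- build_survey_schedule(sw, 8, seed = 21)
  obs <- simulate_observations(ground_truth(dm, tp, 30), sched, seed = 22)
  spec <- fit_spec("dual", n_starts = 4,
                   fixed = list(a = 3, g = 4, ta_min = 0.1,
                                "ta_max_0.25" = 0.9, "ta_max_1" = 0.85))
  fit <- fit_mountain(obs, spec, tp, seed = 5)
  est <- coef(fit)
  expect_lte(est[["chronaxie1"]], 6)
  expect_lte(est[["chronaxie2"]], 6)
  expect_lte(est[["chronaxie1"]], est[["chronaxie2"]])  # label ordering
  expect_identical(est[["a"]], 3)
  expect_identical(est[["ta_max_0.25"]], 0.9)
  # the weight and payoff scale trade off along a ridge under noise, but the
  # surface's effective locations are identified
  fp <- params_from_fit(fit)
  for (d in c(0.25, 1)) {
    el_t <- effective_location_params(dm, d, tp)
    el_f <- effective_location_params(fp, d, tp)
    expect_equal(el_f$f_hm_effective, el_t$f_hm_effective, tolerance = 0.2)
    expect_equal(el_f$p_e_effective, el_t$p_e_effective, tolerance = 0.2)
  }
  # with noiseless data the generating parameters are recovered outright
  obs0 <- simulate_observations(ground_truth(dm, tp, Inf), sched, seed = 22)
  est0 <- coef(fit_mountain(obs0, spec, tp, seed = 5))
  expect_equal(est0[["w"]], 0.6, tolerance = 0.01)
  expect_equal(est0[["chronaxie1"]], 0.15, tolerance = 0.01)
  expect_equal(est0[["chronaxie2"]], 5, tolerance = 0.01)
  expect_equal(est0[["rheobase1"]], 50, tolerance = 0.01)
  expect_equal(est0[["rheobase2"]], 40, tolerance = 0.01)
})

test_that("percentile rule uses order statistics excluding ceil(0.025 B) per tail", {
  set.seed(41)
  x <- rnorm(200)
  ci <- boot_percentile_ci(x)
  s <- sort(x)
  expect_identical(ci[["lower"]], s[6])    # 5 excluded below
  expect_identical(ci[["upper"]], s[195])  # 5 excluded above
  expect_true(all(ci %in% x))
  # B = 1000 reproduces the drop-25-per-tail rule exactly
  y <- rnorm(1000)
  ci1000 <- boot_percentile_ci(y)
  sy <- sort(y)
  expect_identical(unname(ci1000), c(sy[26], sy[975]))
  expect_error(boot_percentile_ci(rnorm(2)), "too few")
})

test_that("bootstrap is reproducible and collapses to zero width without noise", {
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = Inf, seed = 2)  # zero variance per point
  spec <- fit_spec("single", n_starts = 2)
  bt <- bootstrap_fit(obs, spec, tp, B = 8, seed = 13)
  expect_equal(bt$n_redrawn, 0)
  # all resamples identical -> all estimates identical, zero-width CIs
  expect_true(all(vapply(bt$estimates, function(x) max(x) - min(x), numeric(1)) == 0))
  expect_true(all(bt$summary$upper - bt$summary$lower == 0))
  bt2 <- bootstrap_fit(obs, spec, tp, B = 8, seed = 13)
  expect_identical(bt$estimates, bt2$estimates)
})

test_that("shift inference reports paired differences with the stated conventions", {
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = 30, seed = 17)
  bt <- bootstrap_fit(obs, fit_spec("single", n_starts = 2), tp, B = 40, seed = 19)
  sh <- shift_inference(bt)
  expect_equal(attr(sh, "sign_convention"), "long_minus_short")
  expect_equal(sh$parameter, c("f_hm", "p_e", "ta_max"))
  # truth: f_hm falls 180 -> 100 with duration; the long - short shift is negative
  row <- sh[sh$parameter == "f_hm", ]
  expect_lt(row$median_diff, 0)
  expect_true(row$significant)
  # the interval endpoints are order statistics of the difference multiset
  diffs <- bt$estimates$f_hm_1 - bt$estimates$`f_hm_0.25`
  expect_true(all(c(row$lower, row$upper) %in% diffs))
  expect_equal(row$median_diff, median(diffs))

  # degenerate all-zero differences: CI [0,0], not significant
  fake <- bt
  fake$estimates$`p_e_0.25` <- fake$estimates$p_e_1
  sh0 <- shift_inference(fake)
  row0 <- sh0[sh0$parameter == "p_e", ]
  expect_equal(row0$median_diff, 0)
  expect_equal(c(row0$lower, row0$upper), c(0, 0))
  expect_false(row0$significant)
})

test_that("information criteria adjudicate single- versus dual-integrator truths", {
  fixed <- list(a = 3, g = 4, ta_min = 0.1, "ta_max_0.25" = 0.9, "ta_max_1" = 0.85)
  spec_s <- fit_spec("single", n_starts = 3, fixed = fixed)
  spec_d <- fit_spec("dual", n_starts = 3, fixed = fixed)

  # single-integrator truth: the simpler model should win on BIC
  prm <- study_truth_params()
  obs <- simulate_study(prm, noise = 30, seed = 23)
  fits <- list(single = fit_mountain(obs, spec_s, tp, seed = 1),
               dual = fit_mountain(obs, spec_d, tp, seed = 1))
  cmp <- compare_models(obs, fits)
  expect_equal(cmp$model[1], "single")

  # well-separated dual truth: the dual model should win
  dm <- dual_mountain_params(sd_params(50, 0.15), sd_params(40, 5), w = 0.6,
                             price_scale = subjective_price(8),
                             a = 3, g = 4, ta_min = 0.1,
                             durations = c(0.25, 1), ta_max = c(0.9, 0.85))
  el_s <- effective_location_params(dm, 0.25, tp)
  el_l <- effective_location_params(dm, 1, tp)
  sw <- c(build_pseudo_sweeps(list(f_hm = el_s$f_hm_effective,
                                   p_e = el_s$p_e_effective), 0.25, tp = tp),
          build_pseudo_sweeps(list(f_hm = el_l$f_hm_effective,
                                   p_e = el_l$p_e_effective), 1, tp = tp))
  sched <- build_survey_schedule(sw, 8, seed = 31)
  obs_d <- simulate_observations(ground_truth(dm, tp, 30), sched, seed = 32)
  fits_d <- list(single = fit_mountain(obs_d, spec_s, tp, seed = 1),
                 dual = fit_mountain(obs_d, spec_d, tp, seed = 1))
  cmp_d <- compare_models(obs_d, fits_d)
  expect_equal(cmp_d$model[1], "dual")

  # identical fits with equal parameter counts tie exactly
  cmp_t <- compare_models(obs, list(m1 = fits$single, m2 = fits$single))
  expect_equal(cmp_t$aic[1], cmp_t$aic[2])
})
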