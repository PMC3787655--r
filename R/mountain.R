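#' Single-integrator mountain parameters
#'
#' Parameters of the matching-law reward-mountain surface with one
#' temporal integrator. The exponents `a` (payoff sensitivity) and `g`
#' (reward growth) and the floor `ta_min` are shared across train
#' durations; the location parameters `f_hm` (pulse frequency producing a
#' half-maximal reward) and `p_e` (price at which time allocation for a
#' maximal reward sits halfway between floor and ceiling) and the ceiling
#' `ta_max` are per-duration. Locations are stored in objective units
#' (pulses/s and s); the surface evaluation maps them through the
#' frequency-following and subjective-price transforms.
#'
#' @param a Payoff-sensitivity exponent, > 0.
#' @param g Reward-growth exponent, > 0.
#' @param ta_min Time-allocation floor in `[0, 1)`, shared.
#' @param durations Train durations (s), one per block.
#' @param f_hm Half-maximal pulse frequency per duration (pulses/s).
#' @param p_e Half-fall price per duration (s).
#' @param ta_max Time-allocation ceiling per duration, in `(ta_min, 1]`.
#' @return An object of class `single_mountain_params`.
#' @export
single_mountain_params <- function(a, g, ta_min, durations, f_hm, p_e, ta_max) {
  stopifnot(is.numeric(a), is.numeric(g), is.numeric(ta_min),
            is.numeric(durations), is.numeric(f_hm), is.numeric(p_e),
            is.numeric(ta_max))
  n <- length(durations)
  if (length(f_hm) != n || length(p_e) != n || length(ta_max) != n)
    stop("f_hm, p_e and ta_max must have one value per duration", call. = FALSE)
  if (anyDuplicated(durations)) stop("durations must be distinct", call. = FALSE)
  if (a <= 0 || g <= 0) stop("a and g must be positive", call. = FALSE)
  if (ta_min < 0 || any(ta_max > 1) || any(ta_min >= ta_max))
    stop("need 0 <= ta_min < ta_max <= 1 in every duration block", call. = FALSE)
  if (any(durations <= 0) || any(f_hm <= 0) || any(p_e <= 0))
    stop("durations, f_hm and p_e must be positive", call. = FALSE)
  structure(list(a = a, g = g, ta_min = ta_min,
                 durations = as.numeric(durations),
                 f_hm = as.numeric(f_hm), p_e = as.numeric(p_e),
                 ta_max = as.numeric(ta_max)),
            class = "single_mountain_params")
}

#' Dual-integrator mountain parameters
#'
#' Variant in which the rewarding effect is the weighted, pooled output of
#' two integrators, each with its own strength-duration law. `w` is the
#' maximum intensity of integrator 1 as a proportion of the summed maxima
#' (integrator 2 takes `1 - w`). The location along the price axis is
#' governed by `price_scale`, the subjective price at which the payoff of
#' a unit-maximal reward is 1; it plays the role the half-fall subjective
#' price plays in the single-integrator surface and reduces to it when
#' `w = 1`.
#'
#' @param integrator1,integrator2 `sd_params` objects.
#' @param w Weight of integrator 1 in `[0, 1]`.
#' @param price_scale Payoff normaliser (subjective seconds), > 0.
#' @param a,g,ta_min As in [single_mountain_params()], shared.
#' @param durations Train durations (s).
#' @param ta_max Ceiling per duration.
#' @return An object of class `dual_mountain_params`.
#' @export
dual_mountain_params <- function(integrator1, integrator2, w, price_scale,
                                 a, g, ta_min, durations, ta_max) {
  stopifnot(inherits(integrator1, "sd_params"), inherits(integrator2, "sd_params"),
            is.numeric(w), is.numeric(price_scale))
  if (w < 0 || w > 1) stop("w must lie in [0, 1]", call. = FALSE)
  if (price_scale <= 0) stop("price_scale must be positive", call. = FALSE)
  n <- length(durations)
  if (length(ta_max) != n)
    stop("ta_max must have one value per duration", call. = FALSE)
  if (a <= 0 || g <= 0) stop("a and g must be positive", call. = FALSE)
  if (ta_min < 0 || any(ta_max > 1) || any(ta_min >= ta_max))
    stop("need 0 <= ta_min < ta_max <= 1 in every duration block", call. = FALSE)
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  structure(list(integrator1 = integrator1, integrator2 = integrator2,
                 w = w, price_scale = price_scale, a = a, g = g,
                 ta_min = ta_min, durations = as.numeric(durations),
                 ta_max = as.numeric(ta_max)),
            class = "dual_mountain_params")
}

# Index of a duration block, with tolerance for floating-point duration keys.
duration_block <- function(params, duration) {
  i <- which(abs(params$durations - duration) < 1e-9)
  if (length(i) != 1L)
    stop("train duration ", duration, " is not a declared condition", call. = FALSE)
  i
}

#' Reward intensity of a single integrator
#'
#' Logistic-in-log growth of reward intensity with induced firing
#' frequency: `ff^g / (ff^g + ff_hm^g)`, evaluated in log space so large
#' growth exponents do not overflow. Equals 0.5 at `ff = ff_hm`.
#'
#' @param ff Induced firing frequency(ies), >= 0.
#' @param ff_hm Half-maximal firing frequency, > 0.
#' @param g Reward-growth exponent, > 0.
#' @return Intensity fraction(s) in `[0, 1]`.
#' @export
reward_intensity_single <- function(ff, ff_hm, g) {
  stopifnot(is.numeric(ff), is.numeric(ff_hm), is.numeric(g))
  if (any(ff < 0) || ff_hm <= 0 || g <= 0)
    stop("need ff >= 0, ff_hm > 0, g > 0", call. = FALSE)
  out <- numeric(length(ff))
  pos <- ff > 0
  out[pos] <- stats::plogis(g * (log(ff[pos]) - log(ff_hm)))
  out
}

# Matching-law allocation stage shared by all surfaces: TA from log payoff.
# TA = ta_min + (ta_max - ta_min) * V^a / (V^a + 1) with V = exp(log_v).
allocation_from_log_payoff <- function(log_v, a, ta_min, ta_max) {
  frac <- ifelse(is.infinite(log_v) & log_v < 0, 0, stats::plogis(a * log_v))
  ta_min + (ta_max - ta_min) * frac
}

#' Time allocation under the extended single-integrator surface
#'
#' The matching-law surface in transformed coordinates: intensity
#' `U = FF^g/(FF^g + FFhm^g)` with `FF` the induced firing frequency and
#' `FFhm` the image of `f_hm`, payoff `U / (SP/SPe)` with `SP` the
#' subjective price and `SPe` the image of `p_e`, and
#' `TA = (TAmax-TAmin) * U^a/(U^a + (SP/SPe)^a) + TAmin`.
#'
#' @param f Pulse frequency(ies), pulses/s.
#' @param p Price(s), s.
#' @param duration Train duration (s); must be one of the declared blocks.
#' @param params A `single_mountain_params` object.
#' @param tp A `transform_params` bundle.
#' @return Time allocation(s) in `[ta_min, ta_max]`.
#' @export
time_allocation_extended <- function(f, p, duration, params,
                                     tp = transform_params()) {
  stopifnot(inherits(params, "single_mountain_params"),
            inherits(tp, "transform_params"))
  i <- duration_block(params, duration)
  ff <- frequency_following(f, tp$ff)
  ff_hm <- frequency_following(params$f_hm[i], tp$ff)
  u <- reward_intensity_single(ff, ff_hm, params$g)
  sp <- subjective_price(p, tp$sp)
  sp_e <- subjective_price(params$p_e[i], tp$sp)
  log_v <- ifelse(u > 0, log(u) + log(sp_e) - log(sp), -Inf)
  allocation_from_log_payoff(log_v, params$a, params$ta_min, params$ta_max[i])
}

#' Time allocation under the original mountain surface
#'
#' The legacy surface in which the subjective price equals the objective
#' price and the neurons fire once per pulse: [time_allocation_extended()]
#' with both transforms replaced by identities.
#'
#' @inheritParams time_allocation_extended
#' @return Time allocation(s) in `[ta_min, ta_max]`.
#' @export
time_allocation_original <- function(f, p, duration, params) {
  stopifnot(inherits(params, "single_mountain_params"))
  if (any(f < 0) || any(p <= 0)) stop("need f >= 0 and p > 0", call. = FALSE)
  i <- duration_block(params, duration)
  u <- reward_intensity_single(f, params$f_hm[i], params$g)
  log_v <- ifelse(u > 0, log(u) + log(params$p_e[i]) - log(p), -Inf)
  allocation_from_log_payoff(log_v, params$a, params$ta_min, params$ta_max[i])
}

#' Pooled reward intensity of the dual-integrator model
#'
#' `I = w * u1 + (1-w) * u2`, where each `u_i` is the single-integrator
#' intensity with half-maximal firing requirement
#' `FFhm_i(d) = rheobase_i * (1 + chronaxie_i / d)`. When an integrator's
#' requirement at a short duration exceeds the frequency-following
#' plateau, that integrator contributes almost nothing at any attainable
#' firing frequency and the maximum achievable pooled intensity drops
#' toward the other integrator's weight.
#'
#' @param ff Induced firing frequency(ies), >= 0.
#' @param d Train duration (s), > 0.
#' @param params A `dual_mountain_params` object.
#' @return Pooled intensity fraction(s) in `[0, 1]`.
#' @export
reward_intensity_dual <- function(ff, d, params) {
  stopifnot(inherits(params, "dual_mountain_params"))
  if (d <= 0) stop("train duration must be positive", call. = FALSE)
  u1 <- reward_intensity_single(
    ff, half_max_firing_at_duration(d, params$integrator1), params$g)
  u2 <- reward_intensity_single(
    ff, half_max_firing_at_duration(d, params$integrator2), params$g)
  params$w * u1 + (1 - params$w) * u2
}

# The dual model's payoff stage, isolated so the parameterisation can be
# swapped without touching the surface code: V = I * price_scale / SP.
dual_log_payoff <- function(intensity, sp, price_scale) {
  ifelse(intensity > 0, log(intensity) + log(price_scale) - log(sp), -Inf)
}

#' Time allocation under the dual-integrator surface
#'
#' Pooled intensity [reward_intensity_dual()] enters the matching law via
#' the payoff `V = I * price_scale / SP`:
#' `TA = (TAmax-TAmin) * V^a/(V^a + 1) + TAmin`. With `w = 1` and
#' `price_scale` equal to the half-fall subjective price this is
#' algebraically identical to [time_allocation_extended()].
#'
#' @inheritParams time_allocation_extended
#' @param params A `dual_mountain_params` object.
#' @return Time allocation(s) in `[ta_min, ta_max]`.
#' @export
time_allocation_dual <- function(f, p, duration, params,
                                 tp = transform_params()) {
  stopifnot(inherits(params, "dual_mountain_params"),
            inherits(tp, "transform_params"))
  i <- duration_block(params, duration)
  ff <- frequency_following(f, tp$ff)
  intensity <- reward_intensity_dual(ff, duration, params)
  sp <- subjective_price(p, tp$sp)
  log_v <- dual_log_payoff(intensity, sp, params$price_scale)
  allocation_from_log_payoff(log_v, params$a, params$ta_min, params$ta_max[i])
}

#' Maximum achievable reward intensity at a duration
#'
#' The pooled (or single) intensity at the frequency-following plateau:
#' the largest intensity any attainable pulse frequency can produce at the
#' given train duration.
#'
#' @param params A `single_mountain_params` or `dual_mountain_params` object.
#' @param duration Train duration (s).
#' @param tp A `transform_params` bundle.
#' @return Intensity fraction in `[0, 1]`.
#' @export
max_achievable_intensity <- function(params, duration, tp = transform_params()) {
  plateau <- ff_plateau(tp$ff)
  if (inherits(params, "dual_mountain_params")) {
    reward_intensity_dual(plateau, duration, params)
  } else if (inherits(params, "single_mountain_params")) {
    i <- duration_block(params, duration)
    ff_hm <- frequency_following(params$f_hm[i], tp$ff)
    reward_intensity_single(plateau, ff_hm, params$g)
  } else {
    stop("unsupported parameter object", call. = FALSE)
  }
}

# Intensity as a function of pulse frequency, for either surface family.
intensity_at_pulse_frequency <- function(f, duration, params, tp) {
  ff <- frequency_following(f, tp$ff)
  if (inherits(params, "dual_mountain_params")) {
    reward_intensity_dual(ff, duration, params)
  } else {
    i <- duration_block(params, duration)
    ff_hm <- frequency_following(params$f_hm[i], tp$ff)
    reward_intensity_single(ff, ff_hm, params$g)
  }
}

#' Effective location parameters of a mountain surface
#'
#' Derived location parameters that make single- and dual-integrator
#' surfaces comparable. `f_hm_effective` is the pulse frequency at which
#' reward intensity reaches half its maximum achievable value at the given
#' duration (found by monotone root finding on log pulse frequency).
#' `p_e_effective` is the objective price at which time allocation for the
#' maximum achievable intensity lies halfway between floor and ceiling;
#' this is the price whose subjective value equals the payoff normaliser
#' times the achievable intensity. A surface too flat to cross either
#' criterion raises a no-solution error.
#'
#' @param params A `single_mountain_params` or `dual_mountain_params` object.
#' @param duration Train duration (s).
#' @param tp A `transform_params` bundle.
#' @return A list with `f_hm_effective` (pulses/s) and `p_e_effective` (s).
#' @export
effective_location_params <- function(params, duration, tp = transform_params()) {
  i_max <- max_achievable_intensity(params, duration, tp)
  if (i_max <= 0) stop("surface is flat: no half-intensity crossing", call. = FALSE)
  target <- i_max / 2
  fn <- function(logf) intensity_at_pulse_frequency(exp(logf), duration, params, tp) - target
  lo <- log(1e-6)
  hi <- log(tp$ff$f_near_max)
  # intensity is strictly increasing in f and -> i_max only as f -> Inf,
  # so the half crossing is bracketed once fn(hi) > 0; extend if needed
  k <- 0
  while (fn(hi) < 0 && k < 60) { hi <- hi + 1; k <- k + 1 }
  if (fn(lo) > 0 || fn(hi) < 0)
    stop("no half-intensity crossing found", call. = FALSE)
  f_hm_eff <- exp(stats::uniroot(fn, c(lo, hi), tol = 1e-12)$root)

  # halfway TA at maximal achievable intensity <=> payoff V = 1
  scale <- if (inherits(params, "dual_mountain_params")) {
    params$price_scale
  } else {
    subjective_price(params$p_e[duration_block(params, duration)], tp$sp)
  }
  sp_target <- i_max * scale
  if (sp_target <= tp$sp$sp_min)
    stop("halfway allocation unattainable: required subjective price at or below sp_min",
         call. = FALSE)
  p_e_eff <- objective_price_from_subjective(sp_target, tp$sp)
  list(f_hm_effective = f_hm_eff, p_e_effective = p_e_eff)
}

#' Evaluate a mountain surface on a rectangular grid
#'
#' Long-format evaluation over log-spaced pulse-frequency and price axes,
#' one block per declared train duration, suitable for contour plotting or
#' export.
#'
#' @param params A `single_mountain_params` or `dual_mountain_params` object.
#' @param tp A `transform_params` bundle.
#' @param f_range,p_range Length-2 positive ranges for the axes.
#' @param n Grid points per axis.
#' @return A tibble with columns `train_duration_s`, `pulse_frequency_pps`,
#'   `price_s`, `time_allocation`.
#' @export
surface_grid <- function(params, tp = transform_params(),
                         f_range = c(10, 400), p_range = c(0.5, 64), n = 50) {
  stopifnot(length(f_range) == 2L, length(p_range) == 2L,
            all(f_range > 0), all(p_range > 0), n >= 2)
  fs <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n))
  ps <- exp(seq(log(p_range[1]), log(p_range[2]), length.out = n))
  eval_fun <- if (inherits(params, "dual_mountain_params")) {
    function(f, p, d) time_allocation_dual(f, p, d, params, tp)
  } else {
    function(f, p, d) time_allocation_extended(f, p, d, params, tp)
  }
  out <- lapply(params$durations, function(d) {
    grid <- expand.grid(pulse_frequency_pps = fs, price_s = ps,
                        KEEP.OUT.ATTRS = FALSE)
    grid$train_duration_s <- d
    grid$time_allocation <-
      eval_fun(grid$pulse_frequency_pps, grid$price_s, d)
    grid
  })
  tibble::as_tibble(do.call(rbind, out))[
    , c("train_duration_s", "pulse_frequency_pps", "price_s", "time_allocation")]
}
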