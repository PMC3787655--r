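#' Subjective-price transform parameters
#'
#' The map from objective to subjective opportunity cost is a softplus:
#' very low prices are all perceived as roughly `sp_min`, and the subjective
#' price converges on the objective price as the price grows. Defaults are
#' the values estimated in prior psychophysical work and held fixed here.
#'
#' @param sp_min Minimum subjective price (s). Must be > 0.
#' @param sp_bend Abruptness of the transition between the floor and the
#'   rising, identity-like portion (s). Must be > 0.
#' @return An object of class `sp_params`.
#' @export
sp_params <- function(sp_min = 1.75, sp_bend = 0.57) {
  stopifnot(is.numeric(sp_min), length(sp_min) == 1L, is.finite(sp_min),
            is.numeric(sp_bend), length(sp_bend) == 1L, is.finite(sp_bend))
  if (sp_min <= 0 || sp_bend <= 0)
    stop("sp_min and sp_bend must be positive", call. = FALSE)
  structure(list(sp_min = sp_min, sp_bend = sp_bend), class = "sp_params")
}

#' Frequency-following transform parameters
#'
#' Below the transition region each stimulation pulse elicits one action
#' potential in the directly stimulated neurons (firing frequency equals
#' pulse frequency); above it the induced firing frequency saturates.
#'
#' @param f_bend Abruptness of the transition between the rising and flat
#'   segments (pulses/s). Must be > 0.
#' @param f_near_max Midpoint of the transitional region (pulses/s). Must
#'   be > 0.
#' @return An object of class `ff_params`.
#' @export
ff_params <- function(f_bend = 20.63, f_near_max = 342.9) {
  stopifnot(is.numeric(f_bend), length(f_bend) == 1L, is.finite(f_bend),
            is.numeric(f_near_max), length(f_near_max) == 1L, is.finite(f_near_max))
  if (f_bend <= 0 || f_near_max <= 0)
    stop("f_bend and f_near_max must be positive", call. = FALSE)
  structure(list(f_bend = f_bend, f_near_max = f_near_max), class = "ff_params")
}

#' Strength-duration parameters (rheobase and chronaxie)
#'
#' Parameters of the hyperbolic law linking the firing frequency required
#' for a half-maximal reward to the train duration: the rheobase is the
#' requirement at infinitely long trains, and the chronaxie is the duration
#' at which the requirement is twice the rheobase.
#'
#' @param rheobase Asymptotic half-maximal firing frequency (spikes/s), > 0.
#' @param chronaxie Duration at which the requirement doubles (s), > 0.
#' @return An object of class `sd_params`.
#' @export
sd_params <- function(rheobase, chronaxie) {
  stopifnot(is.numeric(rheobase), length(rheobase) == 1L, is.finite(rheobase),
            is.numeric(chronaxie), length(chronaxie) == 1L, is.finite(chronaxie))
  if (rheobase <= 0 || chronaxie <= 0)
    stop("rheobase and chronaxie must be positive", call. = FALSE)
  structure(list(rheobase = rheobase, chronaxie = chronaxie), class = "sd_params")
}

#' Bundle of transform parameters
#'
#' Convenience container pairing the subjective-price and
#' frequency-following parameter sets used throughout the surface
#' evaluations and fits.
#'
#' @param sp An `sp_params` object.
#' @param ff An `ff_params` object.
#' @return An object of class `transform_params`.
#' @export
transform_params <- function(sp = sp_params(), ff = ff_params()) {
  stopifnot(inherits(sp, "sp_params"), inherits(ff, "ff_params"))
  structure(list(sp = sp, ff = ff), class = "transform_params")
}

# Overflow-safe softplus: log(1 + e^x) = max(x, 0) + log1p(e^-|x|).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Inverse softplus on (0, Inf): log(e^s - 1), stable for large s.
inv_softplus <- function(s) {
  out <- s + log(-expm1(-s))
  small <- s < 1e-10
  if (any(small)) out[small] <- log(expm1(s[small]))
  out
}

#' Subjective price of an objective price
#'
#' `SP = SPmin + SPbend * log(1 + exp((P - SPmin)/SPbend))`, evaluated in
#' overflow-safe form. Strictly increasing in `p`, bounded below by
#' `sp_min`, and asymptotically equal to `p` for prices a few bend-widths
#' above the floor.
#'
#' @param p Objective price(s) in seconds; must be >= 0.
#' @param params An `sp_params` object.
#' @return Subjective price(s) in seconds.
#' @export
subjective_price <- function(p, params = sp_params()) {
  stopifnot(inherits(params, "sp_params"), is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0))
    stop("objective price must be finite and non-negative", call. = FALSE)
  params$sp_min + params$sp_bend * softplus((p - params$sp_min) / params$sp_bend)
}

#' Objective price producing a given subjective price
#'
#' Exact inverse of [subjective_price()] via the closed-form softplus
#' inverse. Only subjective prices strictly above the value at `p = 0` are
#' attainable; values at or below `sp_min` (or below the `p = 0` image)
#' raise a no-solution error.
#'
#' @param sp Subjective price(s) in seconds.
#' @param params An `sp_params` object.
#' @return Objective price(s) in seconds satisfying the round trip to
#'   within 1e-8 s.
#' @export
objective_price_from_subjective <- function(sp, params = sp_params()) {
  stopifnot(inherits(params, "sp_params"), is.numeric(sp))
  if (any(!is.finite(sp)) || any(sp <= params$sp_min))
    stop("subjective price must exceed sp_min; no objective price attains it",
         call. = FALSE)
  p <- params$sp_min +
    params$sp_bend * inv_softplus((sp - params$sp_min) / params$sp_bend)
  if (any(p < 0))
    stop("subjective price below the value attained at zero objective price",
         call. = FALSE)
  p
}

#' Plateau of the frequency-following transform
#'
#' The supremum of the induced firing frequency,
#' `Fbend * log(1 + exp(FNearMax/Fbend))`, approached as the pulse
#' frequency grows without bound.
#'
#' @param params An `ff_params` object.
#' @return Plateau firing frequency (spikes/s).
#' @export
ff_plateau <- function(params = ff_params()) {
  stopifnot(inherits(params, "ff_params"))
  params$f_bend * softplus(params$f_near_max / params$f_bend)
}

#' Induced firing frequency for a pulse frequency
#'
#' `FF = Fbend * [log(1+exp(FNearMax/Fbend)) - log(1+exp((FNearMax-F)/Fbend))]`.
#' Approximately one spike per pulse well below the transition region, then
#' saturating at the plateau. Zero at `f = 0` by exact cancellation.
#'
#' @param f Pulse frequency(ies) in pulses/s; must be >= 0.
#' @param params An `ff_params` object.
#' @return Induced firing frequency(ies) in spikes/s.
#' @export
frequency_following <- function(f, params = ff_params()) {
  stopifnot(inherits(params, "ff_params"), is.numeric(f))
  if (any(!is.finite(f)) || any(f < 0))
    stop("pulse frequency must be finite and non-negative", call. = FALSE)
  b <- params$f_bend
  m <- params$f_near_max
  b * (softplus(m / b) - softplus((m - f) / b))
}

#' Pulse frequency required for a target firing frequency
#'
#' Inverse of [frequency_following()]. Firing demands at or above the
#' plateau cannot be met by any pulse frequency; these return a tagged
#' unreachable result rather than an error, because the dropout of an
#' integrator whose demands exceed the frequency-following capability is a
#' meaningful regime of the dual-integrator model.
#'
#' @param ff Target firing frequency(ies) in spikes/s; must be >= 0.
#' @param params An `ff_params` object.
#' @return A list with `pulse_frequency` (numeric, `NA` where unreachable)
#'   and `reachable` (logical).
#' @export
pulse_frequency_for_firing <- function(ff, params = ff_params()) {
  stopifnot(inherits(params, "ff_params"), is.numeric(ff))
  if (any(!is.finite(ff)) || any(ff < 0))
    stop("firing frequency must be finite and non-negative", call. = FALSE)
  b <- params$f_bend
  m <- params$f_near_max
  plateau <- ff_plateau(params)
  reachable <- ff < plateau
  f <- rep(NA_real_, length(ff))
  idx <- which(reachable & ff > 0)
  if (length(idx)) {
    # softplus((m - f)/b) = softplus(m/b) - ff/b, then invert softplus
    s <- (plateau - ff[idx]) / b
    f[idx] <- m - b * inv_softplus(s)
  }
  f[reachable & ff == 0] <- 0
  list(pulse_frequency = f, reachable = reachable)
}

#' Half-maximal firing requirement at a train duration
#'
#' The hyperbolic strength-duration law
#' `FFhm(D) = rheobase * (1 + chronaxie / D)`: short trains demand high
#' firing frequencies; the requirement falls toward the rheobase as the
#' train lengthens, and equals twice the rheobase at `D = chronaxie`.
#'
#' @param d Train duration(s) in seconds; must be > 0.
#' @param params An `sd_params` object.
#' @return Required firing frequency(ies) in spikes/s.
#' @export
half_max_firing_at_duration <- function(d, params) {
  stopifnot(inherits(params, "sd_params"), is.numeric(d))
  if (any(!is.finite(d)) || any(d <= 0))
    stop("train duration must be finite and positive", call. = FALSE)
  params$rheobase * (1 + params$chronaxie / d)
}
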