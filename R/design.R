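#' Span specification for pseudo-sweep construction
#'
#' Controls where the three nine-point pseudo-sweeps sit relative to the
#' mountain's location parameters. Half-spans are in log10 units; with the
#' default 0.75 each sweep covers 1.5 decades, wide enough that roughly
#' three points sit on each performance asymptote. The frequency sweep
#' runs at a fixed low price and the price sweep at a fixed high pulse
#' frequency; the defaults anchor the low price at twice the
#' subjective-price floor and the high frequency just below the midpoint
#' of the frequency-following transition, mirroring the design intent of
#' testing near, but not beyond, the tolerable maximum.
#'
#' @param f_half_span_log10,p_half_span_log10 Half-spans of the axes.
#' @param price_low Constant price of the frequency sweep (s); `NULL`
#'   means `2 * sp_min` of the transform bundle in force.
#' @param f_high Constant pulse frequency of the price sweep (pulses/s);
#'   `NULL` means `0.9 * f_near_max`.
#' @return An object of class `sweep_spans`.
#' @export
sweep_spans <- function(f_half_span_log10 = 0.75, p_half_span_log10 = 0.75,
                        price_low = NULL, f_high = NULL) {
  stopifnot(f_half_span_log10 > 0, p_half_span_log10 > 0)
  structure(list(f_half_span_log10 = f_half_span_log10,
                 p_half_span_log10 = p_half_span_log10,
                 price_low = price_low, f_high = f_high),
            class = "sweep_spans")
}

#' Build the three pseudo-sweeps for one train duration
#'
#' Each pseudo-sweep is nine points equally spaced along a straight line
#' in (log frequency, log price) space. The frequency sweep runs parallel
#' to the frequency axis at a low price; the price sweep runs parallel to
#' the price axis at a high frequency; the radial sweep runs diagonally
#' from (high frequency, low price) to (low frequency, high price) through
#' the point defined by the two location parameters.
#'
#' @param center Named list or vector with `f_hm` (pulses/s) and `p_e` (s).
#' @param duration Train duration (s).
#' @param spans A [sweep_spans()] object.
#' @param tp A `transform_params` bundle (used only for span anchors).
#' @return A list of three `pseudo_sweep` objects (`frequency`, `price`,
#'   `radial`), each with a 9-row `points` tibble.
#' @export
build_pseudo_sweeps <- function(center, duration, spans = sweep_spans(),
                                tp = transform_params()) {
  stopifnot(inherits(spans, "sweep_spans"), inherits(tp, "transform_params"))
  f_hm <- center[["f_hm"]]
  p_e <- center[["p_e"]]
  if (is.null(f_hm) || is.null(p_e) || f_hm <= 0 || p_e <= 0)
    stop("center must supply positive f_hm and p_e", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  price_low <- spans$price_low %||% (2 * tp$sp$sp_min)
  f_high <- spans$f_high %||% (0.9 * tp$ff$f_near_max)
  s <- seq(-1, 1, length.out = 9)

  mk <- function(type, f, p) {
    structure(list(sweep_type = type, train_duration = duration,
                   points = tibble::tibble(point_index = 1:9,
                                           pulse_frequency = f, price = p)),
              class = "pseudo_sweep")
  }
  list(
    frequency = mk("frequency",
                   10^(log10(f_hm) + spans$f_half_span_log10 * s),
                   rep(price_low, 9)),
    price = mk("price", rep(f_high, 9),
               10^(log10(p_e) + spans$p_half_span_log10 * s)),
    # descending diagonal: high frequency / low price -> low / high,
    # passing exactly through (f_hm, p_e) at its centre point
    radial = mk("radial",
                10^(log10(f_hm) - spans$f_half_span_log10 * s),
                10^(log10(p_e) + spans$p_half_span_log10 * s))
  )
}

# Deterministic child seed for a survey's own RNG stream.
child_seed <- function(root_seed, k) {
  (as.integer(root_seed) %% 1000003L) * 2011L + 7919L * as.integer(k)
}

#' Build the randomised survey schedule
#'
#' The elements of all six pseudo-sweeps (three per train duration) are
#' combined in a virtual urn — the five central points of each sweep
#' appearing twice, the four extreme points once — and drawn at random
#' without replacement until the urn is empty, completing one survey.
#' After `n_surveys = 8` surveys every central point has 16 scheduled
#' observations and every extreme point 8.
#'
#' @param sweeps List of six `pseudo_sweep` objects, three per duration.
#' @param n_surveys Number of surveys, default 8.
#' @param seed Root seed; each survey draws from its own child stream.
#' @return A `survey_schedule`: a tibble with columns `survey`, `trial`,
#'   `sweep_type`, `train_duration_s`, `point_index`,
#'   `pulse_frequency_pps`, `price_s`.
#' @export
build_survey_schedule <- function(sweeps, n_surveys = 8, seed = 1L) {
  if (!is.list(sweeps) || length(sweeps) != 6L ||
      !all(vapply(sweeps, inherits, logical(1), "pseudo_sweep")))
    stop("need exactly 6 pseudo-sweeps (3 per train duration)", call. = FALSE)
  durs <- unique(vapply(sweeps, function(x) x$train_duration, numeric(1)))
  if (length(durs) != 2L)
    stop("the 6 pseudo-sweeps must cover exactly 2 train durations", call. = FALSE)
  reps <- c(1, 1, 2, 2, 2, 2, 2, 1, 1)  # central 5 sampled twice as often
  urn <- dplyr::bind_rows(lapply(sweeps, function(sw) {
    pts <- sw$points[rep(1:9, times = reps), ]
    tibble::tibble(sweep_type = sw$sweep_type,
                   train_duration_s = sw$train_duration,
                   point_index = pts$point_index,
                   pulse_frequency_pps = pts$pulse_frequency,
                   price_s = pts$price)
  }))
  out <- lapply(seq_len(n_surveys), function(k) {
    ord <- withr::with_seed(child_seed(seed, k), sample.int(nrow(urn)))
    drawn <- urn[ord, ]
    drawn$survey <- k
    drawn$trial <- seq_len(nrow(urn))
    drawn
  })
  sched <- dplyr::bind_rows(out)[, c("survey", "trial", "sweep_type",
                                     "train_duration_s", "point_index",
                                     "pulse_frequency_pps", "price_s")]
  structure(sched, class = c("survey_schedule", class(sched)), seed = seed)
}

#' Ground truth for synthetic data generation
#'
#' Bundles the generating mountain, the transform constants, and the
#' bounded-noise dispersion used to emulate a rat's trial-to-trial
#' variability. Time allocation is a proportion, so noise is beta around
#' the surface value with concentration `noise_concentration` (shape sum);
#' larger is less noisy, `Inf` means noiseless.
#'
#' @param model A `single_mountain_params` or `dual_mountain_params` object.
#' @param tp A `transform_params` bundle.
#' @param noise_concentration Beta concentration, > 0 (default 30 gives a
#'   trial-to-trial SD of about 0.09 at mid-range allocations, comparable
#'   to well-trained operant performance).
#' @param subject Subject label for the emitted observations.
#' @param heteroscedastic If `TRUE`, concentration is halved on the rising
#'   portion of the surface (where non-asymptotic performance is expected
#'   to be more variable); default `FALSE`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(model, tp = transform_params(),
                         noise_concentration = 30, subject = "synthetic-1",
                         heteroscedastic = FALSE) {
  stopifnot(inherits(model, "single_mountain_params") ||
              inherits(model, "dual_mountain_params"),
            inherits(tp, "transform_params"))
  if (!is.numeric(noise_concentration) || noise_concentration <= 0)
    stop("noise_concentration must be positive (may be Inf)", call. = FALSE)
  structure(list(model = model, tp = tp,
                 noise_concentration = noise_concentration,
                 subject = subject, heteroscedastic = heteroscedastic),
            class = "ground_truth")
}

# Surface evaluation dispatching on the truth's model class.
truth_surface <- function(truth, f, p, d) {
  if (inherits(truth$model, "dual_mountain_params")) {
    time_allocation_dual(f, p, d, truth$model, truth$tp)
  } else {
    time_allocation_extended(f, p, d, truth$model, truth$tp)
  }
}

#' Simulate time-allocation observations over a schedule
#'
#' For every scheduled trial, draws a time allocation from a beta law on
#' `[0, 1]` whose mean is the ground-truth surface value at that design
#' point and whose dispersion is set by the truth's noise concentration.
#' Deterministic under `seed`.
#'
#' @param truth A [ground_truth()] object.
#' @param schedule A `survey_schedule`.
#' @param seed Integer seed.
#' @return An observation tibble with columns `subject`,
#'   `train_duration_s`, `pulse_frequency_pps`, `price_s`, `sweep_type`,
#'   `survey`, `time_allocation`.
#' @export
simulate_observations <- function(truth, schedule, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(schedule, "survey_schedule"))
  mu <- numeric(nrow(schedule))
  # evaluate per duration (surfaces take a scalar duration)
  for (d in unique(schedule$train_duration_s)) {
    idx <- schedule$train_duration_s == d
    mu[idx] <- truth_surface(truth, schedule$pulse_frequency_pps[idx],
                             schedule$price_s[idx], d)
  }
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  phi <- rep(truth$noise_concentration, length(mu))
  if (isTRUE(truth$heteroscedastic)) {
    lo <- min(mu) + 0.1 * (max(mu) - min(mu))
    hi <- max(mu) - 0.1 * (max(mu) - min(mu))
    phi[mu > lo & mu < hi] <- phi[mu > lo & mu < hi] / 2
  }
  ta <- withr::with_seed(as.integer(seed), {
    if (is.infinite(truth$noise_concentration)) mu
    else stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  })
  tibble::tibble(subject = truth$subject,
                 train_duration_s = schedule$train_duration_s,
                 pulse_frequency_pps = schedule$pulse_frequency_pps,
                 price_s = schedule$price_s,
                 sweep_type = schedule$sweep_type,
                 survey = schedule$survey,
                 time_allocation = ta)
}

#' Behaviour policy for event-level simulation
#'
#' A two-state (work/leisure) alternating-renewal dwell process with
#' exponential bouts. The mean work-bout length is fixed; the mean leisure
#' bout is chosen so that the stationary work fraction equals the target
#' time allocation, so averaging computed TA over trials recovers the
#' surface value.
#'
#' @param mean_work_bout Mean duration of a work bout (s), default 12.
#' @param n_rewards Rewards the trial is sized for (trial time with the
#'   lever available equals `n_rewards * price`), default 25.
#' @return An object of class `behavior_policy`.
#' @export
behavior_policy <- function(mean_work_bout = 12, n_rewards = 25) {
  stopifnot(mean_work_bout > 0, n_rewards >= 1)
  structure(list(mean_work_bout = mean_work_bout, n_rewards = n_rewards),
            class = "behavior_policy")
}

# Simulate one trial's lever events given a target stationary TA.
# Available (lever-extended) time is n_rewards * price; each reward
# retracts the lever for `blackout` seconds of wall time during which no
# events occur.
simulate_one_trial_events <- function(ta_target, price, blackout, policy) {
  avail_total <- policy$n_rewards * price
  mw <- policy$mean_work_bout
  always <- ta_target >= 1 - 1e-9
  never <- ta_target <= 1e-9
  ml <- if (always || never) NA_real_ else mw * (1 - ta_target) / ta_target

  t <- 0          # wall clock
  avail <- 0      # lever-available time consumed
  held_since_reward <- 0
  events <- list(list(t = 0, kind = "trial_start"))
  push <- function(tt, kind) events[[length(events) + 1L]] <<- list(t = tt, kind = kind)

  # stationary start: in-work with probability ta_target (exponential
  # bouts are memoryless, so residual bout lengths are exponential too)
  working <- if (always) TRUE else if (never) FALSE else stats::runif(1) < ta_target
  if (working) push(t, "press")
  bout_left <- if (always || never) Inf else stats::rexp(1, 1 / (if (working) mw else ml))

  while (avail < avail_total) {
    room <- avail_total - avail
    if (working) {
      to_reward <- price - held_since_reward
      step <- min(bout_left, to_reward, room)
      t <- t + step; avail <- avail + step
      held_since_reward <- held_since_reward + step
      bout_left <- bout_left - step
      if (step == to_reward && held_since_reward >= price - 1e-12) {
        push(t, "reward_delivered")
        push(t, "release")       # lever retracts during blackout
        t <- t + blackout
        held_since_reward <- 0
        if (avail >= avail_total - 1e-12) break
        if (bout_left > 1e-12) {
          push(t, "press")       # still in a work bout: resume holding
        } else {
          working <- FALSE
          bout_left <- if (always) Inf else stats::rexp(1, 1 / ml)
        }
        next
      }
      if (bout_left <= 1e-12 && avail < avail_total - 1e-12) {
        push(t, "release")
        working <- FALSE
        bout_left <- stats::rexp(1, 1 / ml)
      }
    } else {
      step <- min(bout_left, room)
      t <- t + step; avail <- avail + step
      bout_left <- bout_left - step
      if (bout_left <= 1e-12 && avail < avail_total - 1e-12) {
        push(t, "press")
        working <- TRUE
        bout_left <- if (always) Inf else stats::rexp(1, 1 / mw)
      }
    }
  }
  if (working && events[[length(events)]]$kind != "release") push(t, "release")
  push(t, "trial_end")
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(t = e$t, kind = e$kind)))
  df[order(df$t, seq_len(nrow(df))), ]
}

#' Simulate event-level trial streams over a schedule
#'
#' Emits, for every scheduled test trial, a `trial_record` with an
#' alternating press/release stream from the two-state dwell process of
#' [behavior_policy()], flanked by a leading bracket trial (maximal
#' frequency, near-ceiling behaviour) and a trailing bracket trial
#' (sub-threshold frequency, near-floor behaviour), as in the bracketed
#' triad protocol. Passing the streams through
#' [compute_time_allocation()] and averaging recovers the ground-truth
#' surface within Monte Carlo error.
#'
#' @param truth A [ground_truth()] object.
#' @param schedule A `survey_schedule`.
#' @param policy A [behavior_policy()].
#' @param seed Integer seed.
#' @param blackout Blackout delay (s), default 2.
#' @return A list of `trial_record`s in presentation order
#'   (leading bracket, test, trailing bracket, ...).
#' @export
simulate_trial_events <- function(truth, schedule, policy = behavior_policy(),
                                  seed = 1L, blackout = 2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(schedule, "survey_schedule"),
            inherits(policy, "behavior_policy"))
  mu <- numeric(nrow(schedule))
  for (d in unique(schedule$train_duration_s)) {
    idx <- schedule$train_duration_s == d
    mu[idx] <- truth_surface(truth, schedule$pulse_frequency_pps[idx],
                             schedule$price_s[idx], d)
  }
  f_max <- max(schedule$pulse_frequency_pps)
  withr::with_seed(as.integer(seed), {
    out <- vector("list", 3L * nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      sv <- schedule$survey[i]
      lead <- trial_record(
        trial_id = sprintf("s%02d-t%03d-lead", sv, schedule$trial[i]),
        role = "leading_bracket",
        stimulus = list(pulse_frequency = f_max, price = 1, train_duration = 0.5),
        events = simulate_one_trial_events(0.97, 1, blackout, policy),
        blackout = blackout, survey = sv)
      test <- trial_record(
        trial_id = sprintf("s%02d-t%03d-test", sv, schedule$trial[i]),
        role = "test",
        stimulus = list(pulse_frequency = schedule$pulse_frequency_pps[i],
                        price = schedule$price_s[i],
                        train_duration = schedule$train_duration_s[i]),
        events = simulate_one_trial_events(mu[i], schedule$price_s[i],
                                           blackout, policy),
        blackout = blackout, survey = sv)
      trail <- trial_record(
        trial_id = sprintf("s%02d-t%03d-trail", sv, schedule$trial[i]),
        role = "trailing_bracket",
        stimulus = list(pulse_frequency = 1, price = 1, train_duration = 0.5),
        events = simulate_one_trial_events(0.03, 1, blackout, policy),
        blackout = blackout, survey = sv)
      out[[3L * i - 2L]] <- lead
      out[[3L * i - 1L]] <- test
      out[[3L * i]] <- trail
    }
    out
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
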