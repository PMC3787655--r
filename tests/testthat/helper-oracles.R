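# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately naive transcriptions or brute-force sweeps, kept separate
# from the package's stabilised implementations.

# Naive (non-stabilised) transcriptions of the transform formulas; they
# overflow for large arguments, which the tests avoid.
naive_subjective_price <- function(p, sp_min = 1.75, sp_bend = 0.57) {
  sp_min + sp_bend * log(1 + exp((p - sp_min) / sp_bend))
}

naive_frequency_following <- function(f, f_bend = 20.63, f_near_max = 342.9) {
  f_bend * (log(1 + exp(f_near_max / f_bend)) -
              log(1 + exp((f_near_max - f) / f_bend)))
}

naive_half_max_firing <- function(d, rheobase, chronaxie) {
  rheobase * (1 + chronaxie / d)
}

# Naive term-by-term transcription of the extended surface.
naive_time_allocation_extended <- function(f, p, a, g, ta_min, ta_max,
                                           f_hm, p_e) {
  ff <- naive_frequency_following(f)
  ff_hm <- naive_frequency_following(f_hm)
  u <- ff^g / (ff^g + ff_hm^g)
  sp <- naive_subjective_price(p)
  sp_e <- naive_subjective_price(p_e)
  (ta_max - ta_min) * u^a / (u^a + (sp / sp_e)^a) + ta_min
}

# Brute-force event-stream oracle: partitions the trial into elementary
# intervals at every event boundary and classifies each by first
# principles, independently of the package's interval arithmetic.
oracle_time_allocation <- function(trial) {
  ev <- trial$events
  t0 <- min(ev$t[ev$kind == "trial_start"], ev$t, 0)
  t1 <- max(ev$t[ev$kind == "trial_end"], ev$t)
  presses <- ev$t[ev$kind == "press"]
  releases <- ev$t[ev$kind == "release"]
  rewards <- ev$t[ev$kind == "reward_delivered"]
  if (length(rewards) == 0L) return(NA_real_)
  hold_end <- c(releases, if (length(presses) > length(releases)) t1)

  cuts <- sort(unique(c(t0, t1, presses, hold_end, rewards,
                        rewards + trial$blackout,
                        c(presses[-1], if (length(presses) == length(releases)) t1))))
  cuts <- cuts[cuts >= t0 & cuts <= t1]
  num <- den <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    m <- (cuts[i] + cuts[i + 1L]) / 2
    len <- cuts[i + 1L] - cuts[i]
    if (m < min(rewards)) next
    if (any(m >= rewards & m < rewards + trial$blackout)) next
    den <- den + len
    holding <- any(m >= presses & m < hold_end[seq_along(presses)])
    work <- holding
    if (!holding && length(releases)) {
      nxt <- c(presses[-1], if (length(presses) == length(releases)) t1)
      for (j in seq_along(releases)) {
        if (j <= length(nxt) && m >= releases[j] && m < nxt[j]) {
          work <- (nxt[j] - releases[j]) < trial$tap_threshold
          break
        }
      }
    }
    if (work) num <- num + len
  }
  if (den <= 0) return(NA_real_)
  min(max(num / den, 0), 1)
}

# Random but structurally valid lever-event stream for property tests.
random_trial <- function(seed, blackout = 2, tap_threshold = 1) {
  set.seed(seed)
  t_end <- runif(1, 20, 120)
  n_bouts <- sample(0:8, 1)
  times <- sort(runif(2 * n_bouts, 0, t_end))
  presses <- times[seq_len(n_bouts) * 2 - 1]
  releases <- times[seq_len(n_bouts) * 2]
  # rewards can only occur while the lever is held
  rewards <- numeric()
  for (i in seq_len(n_bouts)) {
    if (runif(1) < 0.6) {
      k <- sample(1:2, 1)
      rewards <- c(rewards, sort(runif(k, presses[i], releases[i])))
    }
  }
  ev <- rbind(
    data.frame(t = 0, kind = "trial_start"),
    if (n_bouts) data.frame(t = presses, kind = "press"),
    if (n_bouts) data.frame(t = releases, kind = "release"),
    if (length(rewards)) data.frame(t = rewards, kind = "reward_delivered"),
    data.frame(t = t_end, kind = "trial_end"))
  ev <- ev[order(ev$t), ]
  trial_record(trial_id = paste0("rnd", seed), events = ev,
               blackout = blackout, tap_threshold = tap_threshold)
}

# Canonical two-duration study fixture used by design/fit tests.
study_truth_params <- function(f_hm = c(180, 100), p_e = c(8, 8),
                               ta_max = c(0.9, 0.85), a = 3, g = 4,
                               ta_min = 0.1) {
  single_mountain_params(a = a, g = g, ta_min = ta_min,
                         durations = c(0.25, 1),
                         f_hm = f_hm, p_e = p_e, ta_max = ta_max)
}

study_schedule <- function(truth_par, tp = transform_params(), n_surveys = 8,
                           seed = 42) {
  sw <- c(build_pseudo_sweeps(list(f_hm = truth_par$f_hm[1],
                                   p_e = truth_par$p_e[1]), 0.25, tp = tp),
          build_pseudo_sweeps(list(f_hm = truth_par$f_hm[2],
                                   p_e = truth_par$p_e[2]), 1, tp = tp))
  build_survey_schedule(sw, n_surveys = n_surveys, seed = seed)
}

simulate_study <- function(truth_par, noise = 30, seed = 1,
                           tp = transform_params(), schedule_seed = 42) {
  sched <- study_schedule(truth_par, tp, seed = schedule_seed)
  simulate_observations(ground_truth(truth_par, tp, noise), sched, seed = seed)
}
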