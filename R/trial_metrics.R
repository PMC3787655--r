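# Interval utilities on the real line. Intervals are two-column matrices
# (start, end), possibly empty; all operations return canonical (sorted,
# disjoint) interval sets.

interval_set <- function(start = numeric(), end = numeric()) {
  m <- cbind(start, end)
  m[m[, 2] > m[, 1], , drop = FALSE]
}

interval_union <- function(m) {
  if (nrow(m) <= 1L) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

interval_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_set())
  pieces <- lapply(seq_len(nrow(a)), function(i) {
    s <- pmax(a[i, 1], b[, 1])
    e <- pmin(a[i, 2], b[, 2])
    interval_set(s, e)
  })
  interval_union(do.call(rbind, pieces))
}

interval_diff <- function(a, b) {
  # a minus b, both canonical
  if (nrow(a) == 0L) return(a)
  if (nrow(b) == 0L) return(a)
  out <- interval_set()
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      new <- interval_set()
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) {
          new <- rbind(new, segs[k, ])
        } else {
          if (bs > s) new <- rbind(new, c(s, bs))
          if (be < e) new <- rbind(new, c(be, e))
        }
      }
      segs <- new
      if (nrow(segs) == 0L) break
    }
    out <- rbind(out, segs)
  }
  interval_union(out)
}

interval_length <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2] - m[, 1])

#' Construct a trial record
#'
#' A single trial of the cumulative handling-time schedule: a stimulus
#' specification plus the time-stamped lever-event stream. Events are a
#' data frame with columns `t` (seconds from trial start) and `kind`, one
#' of `press`, `release`, `reward_delivered`, `trial_start`, `trial_end`.
#'
#' @param trial_id Identifier.
#' @param role One of `test`, `leading_bracket`, `trailing_bracket`.
#' @param stimulus Named list with `pulse_frequency`, `price`,
#'   `train_duration`.
#' @param events Data frame of lever events.
#' @param blackout Blackout delay after each reward (s), default 2.
#' @param tap_threshold Release gaps strictly shorter than this count as
#'   work (s), default 1.
#' @param survey Optional survey index for stability reporting.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, role = "test", stimulus = list(),
                         events, blackout = 2, tap_threshold = 1,
                         survey = NA_integer_) {
  role <- match.arg(role, c("test", "leading_bracket", "trailing_bracket"))
  stopifnot(is.data.frame(events), all(c("t", "kind") %in% names(events)),
            blackout >= 0, tap_threshold >= 0)
  if (is.unsorted(events$t)) stop("events must be time-ordered", call. = FALSE)
  structure(list(trial_id = trial_id, role = role, stimulus = stimulus,
                 events = events, blackout = blackout,
                 tap_threshold = tap_threshold, survey = survey),
            class = "trial_record")
}

#' Time allocation of a trial from its lever-event stream
#'
#' The dependent measure: the proportion of corrected trial time spent
#' working. Work time is the total lever-hold time plus all release gaps
#' strictly shorter than the tap threshold (brief "taps" during which the
#' animal is still engaged). The denominator is the trial time minus every
#' blackout interval (reconstructed as `[reward, reward + blackout]`) and
#' minus the span before the first reward delivery, during which the
#' animal has no information about the reward on offer; the same spans are
#' excluded from work time. Release gaps spanning a reward delivery are
#' classified by their total length (and the portion inside excluded spans
#' is discounted either way).
#'
#' @param trial A `trial_record`.
#' @return Time allocation in `[0, 1]`, or a tagged `NA` (attribute
#'   `undefined = TRUE`) for trials in which no reward was delivered.
#' @export
compute_time_allocation <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  ev <- trial$events
  t0 <- if (any(ev$kind == "trial_start")) min(ev$t[ev$kind == "trial_start"]) else min(ev$t, 0)
  t1 <- if (any(ev$kind == "trial_end")) max(ev$t[ev$kind == "trial_end"]) else max(ev$t)
  presses <- ev$t[ev$kind == "press"]
  releases <- ev$t[ev$kind == "release"]
  rewards <- ev$t[ev$kind == "reward_delivered"]

  # presses and releases must alternate, starting with a press
  np <- length(presses); nr <- length(releases)
  if (nr > np || np > nr + 1L)
    stop("malformed event stream: presses and releases do not alternate",
         call. = FALSE)
  if (np > 0L) {
    paired <- c(rbind(presses, c(releases, if (np > nr) t1)))
    if (is.unsorted(paired, strictly = FALSE))
      stop("malformed event stream: presses and releases do not alternate",
           call. = FALSE)
  }

  if (length(rewards) == 0L)
    return(structure(NA_real_, undefined = TRUE))

  holds <- if (np > 0L) {
    interval_set(presses, c(releases, if (np > nr) t1))
  } else interval_set()
  gaps <- if (nr > 0L) {
    gap_end <- c(presses[-1L], if (np == nr) t1)[seq_len(nr)]
    keep <- (gap_end - releases) < trial$tap_threshold
    interval_set(releases[keep], gap_end[keep])
  } else interval_set()

  window <- interval_set(t0, t1)
  excl <- interval_union(rbind(
    interval_set(t0, min(rewards)),
    interval_set(rewards, pmin(rewards + trial$blackout, t1))))
  excl <- interval_intersect(excl, window)

  denom <- interval_length(window) - interval_length(excl)
  if (denom <= 0) return(structure(NA_real_, undefined = TRUE))
  work <- interval_union(rbind(holds, gaps))
  work <- interval_diff(interval_intersect(work, window), excl)
  min(max(interval_length(work) / denom, 0), 1)
}

#' Per-survey bracket-trial stability report
#'
#' Bracket trials flank each test trial with a very strong (leading) and a
#' very weak (trailing) reward; stable performance shows consistently high
#' time allocation on leading brackets and consistently low on trailing
#' ones. Reports per-survey means and a pass flag.
#'
#' @param trials List of `trial_record`s (only bracket roles are used).
#' @param high_thresh Leading brackets must average at least this, default
#'   0.8.
#' @param low_thresh Trailing brackets must average at most this, default
#'   0.2.
#' @return A tibble with columns `survey`, `mean_leading`, `mean_trailing`,
#'   `n_leading`, `n_trailing`, `pass`. Empty (with a warning) if no
#'   bracket trials are present.
#' @export
bracket_stability_report <- function(trials, high_thresh = 0.8,
                                     low_thresh = 0.2) {
  stopifnot(is.list(trials))
  roles <- vapply(trials, function(x) x$role, character(1))
  keep <- roles %in% c("leading_bracket", "trailing_bracket")
  if (!any(keep)) {
    warning("no bracket trials supplied; empty stability report")
    return(tibble::tibble(survey = integer(), mean_leading = numeric(),
                          mean_trailing = numeric(), n_leading = integer(),
                          n_trailing = integer(), pass = logical()))
  }
  ta <- vapply(trials[keep], function(x) as.numeric(compute_time_allocation(x)),
               numeric(1))
  ta[is.na(ta)] <- 0  # no reward earned on a bracket trial: scored as no work
  df <- tibble::tibble(
    survey = vapply(trials[keep], function(x) as.integer(x$survey), integer(1)),
    role = roles[keep],
    ta = ta)
  out <- lapply(sort(unique(df$survey)), function(s) {
    lead <- df$ta[df$survey == s & df$role == "leading_bracket"]
    trail <- df$ta[df$survey == s & df$role == "trailing_bracket"]
    tibble::tibble(
      survey = s,
      mean_leading = if (length(lead)) mean(lead, na.rm = TRUE) else NA_real_,
      mean_trailing = if (length(trail)) mean(trail, na.rm = TRUE) else NA_real_,
      n_leading = length(lead), n_trailing = length(trail),
      pass = isTRUE(mean(lead, na.rm = TRUE) >= high_thresh) &&
        isTRUE(mean(trail, na.rm = TRUE) <= low_thresh))
  })
  dplyr::bind_rows(out)
}
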