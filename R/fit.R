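#' Specification of a mountain fit
#'
#' Declares which surface family to fit, how parameters are shared across
#' train-duration conditions, box bounds, fixed-parameter assignments, and
#' optimizer settings. The default sharing follows the joint-fit
#' convention: only the location parameters (`f_hm`, `p_e` for the
#' single-integrator surface) and the ceiling `ta_max` are free to vary
#' across durations; `a`, `g` and `ta_min` are common. For the
#' dual-integrator surface the strength-duration parameters, weight and
#' payoff scale are shared by construction (duration dependence enters
#' through the strength-duration law), `a`, `g`, `ta_min` and the
#' per-duration `ta_max` are normally supplied in `fixed`, and the
#' chronaxies are capped at `chronaxie_max` (default 6 s).
#'
#' @param model `"single"` or `"dual"`.
#' @param shared Character vector of parameter bases shared across
#'   durations.
#' @param fixed Named list of fixed assignments. Per-duration parameters
#'   use suffixed names, e.g. `ta_max_0.25`.
#' @param bounds Named list of length-2 numeric bounds overriding the
#'   defaults, keyed by parameter base (e.g. `list(p_e = c(0.1, 100))`).
#' @param chronaxie_max Upper bound on chronaxies (s), dual model only.
#' @param n_starts Number of multistart initialisations.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(model = c("single", "dual"),
                     shared = NULL, fixed = list(), bounds = list(),
                     chronaxie_max = 6, n_starts = 8, maxiter = 200) {
  model <- match.arg(model)
  default_shared <- if (model == "single") c("a", "g", "ta_min")
  else c("rheobase1", "rheobase2", "chronaxie1", "chronaxie2",
         "w", "price_scale", "a", "g", "ta_min")
  shared <- shared %||% default_shared
  bases <- if (model == "single") c("a", "g", "ta_min", "f_hm", "p_e", "ta_max")
  else c("rheobase1", "rheobase2", "chronaxie1", "chronaxie2",
         "w", "price_scale", "a", "g", "ta_min", "ta_max")
  if (!all(shared %in% bases))
    stop("unknown parameter in `shared`", call. = FALSE)
  if (model == "dual" &&
      !all(c("rheobase1", "rheobase2", "chronaxie1", "chronaxie2",
             "w", "price_scale") %in% shared))
    stop("dual-integrator structural parameters must be shared", call. = FALSE)
  structure(list(model = model, shared = shared, bases = bases,
                 fixed = fixed, bounds = bounds,
                 chronaxie_max = chronaxie_max,
                 n_starts = as.integer(n_starts), maxiter = as.integer(maxiter)),
            class = "fit_spec")
}

default_bounds <- function(base, spec) {
  if (!is.null(spec$bounds[[base]])) return(spec$bounds[[base]])
  switch(base,
         a = c(0.2, 20), g = c(0.2, 20),
         ta_min = c(0, 0.4), ta_max = c(0.4, 1),
         f_hm = c(1, 2000), p_e = c(0.05, 500),
         rheobase1 = c(1, 2000), rheobase2 = c(1, 2000),
         chronaxie1 = c(1e-3, spec$chronaxie_max),
         chronaxie2 = c(1e-3, spec$chronaxie_max),
         w = c(0, 1), price_scale = c(0.2, 2000),
         stop("no default bounds for ", base, call. = FALSE))
}

par_transform <- function(base) {
  if (base %in% c("ta_min", "ta_max", "w")) "id" else "log"
}

par_name <- function(base, duration = NA) {
  if (is.na(duration)) base else sprintf("%s_%g", base, duration)
}

# One row per model parameter instance: name, base, duration, transform,
# bounds, and fixed value (NA when free).
build_par_table <- function(spec, durations) {
  rows <- list()
  for (base in spec$bases) {
    durs <- if (base %in% spec$shared) NA_real_ else durations
    for (d in durs) {
      nm <- par_name(base, d)
      b <- default_bounds(base, spec)
      fx <- spec$fixed[[nm]] %||% NA_real_
      rows[[nm]] <- data.frame(name = nm, base = base, duration = d,
                               trans = par_transform(base),
                               lower = b[1], upper = b[2],
                               fixed = as.numeric(fx))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

to_opt <- function(x, trans) ifelse(trans == "log", log(x), x)
from_opt <- function(x, trans) ifelse(trans == "log", exp(x), x)

# Natural-unit named vector from free theta (optimizer space) + table.
natural_params <- function(theta, pt) {
  out <- pt$fixed
  free <- is.na(pt$fixed)
  out[free] <- from_opt(theta, pt$trans[free])
  names(out) <- pt$name
  out
}

# Fast surface evaluation over precomputed observation vectors.
eval_model_ta <- function(nat, model, di, durations, ff_obs, sp_obs, tp) {
  a <- nat[["a"]]; g <- nat[["g"]]; ta_min <- nat[["ta_min"]]
  get_d <- function(base) {
    if (!is.na(match(base, names(nat)))) rep(nat[[base]], length(durations))
    else vapply(durations, function(d) nat[[par_name(base, d)]], numeric(1))
  }
  ta_max <- get_d("ta_max")
  log_ff <- ifelse(ff_obs > 0, log(ff_obs), -Inf)
  if (model == "single") {
    ffhm <- frequency_following(get_d("f_hm"), tp$ff)
    spe <- subjective_price(get_d("p_e"), tp$sp)
    u <- stats::plogis(g * (log_ff - log(ffhm[di])))
    log_scale <- log(spe[di])
  } else {
    ffhm1 <- nat[["rheobase1"]] * (1 + nat[["chronaxie1"]] / durations)
    ffhm2 <- nat[["rheobase2"]] * (1 + nat[["chronaxie2"]] / durations)
    w <- nat[["w"]]
    u <- w * stats::plogis(g * (log_ff - log(ffhm1[di]))) +
      (1 - w) * stats::plogis(g * (log_ff - log(ffhm2[di])))
    log_scale <- log(nat[["price_scale"]])
  }
  log_v <- ifelse(u > 0, log(u) + log_scale - log(sp_obs), -Inf)
  ta_min + (ta_max[di] - ta_min) * stats::plogis(a * log_v)
}

# Data-driven initial guesses in natural units, one per free parameter.
init_guess <- function(obs, pt, spec, durations, tp) {
  ta <- obs$time_allocation
  ta_min0 <- max(stats::quantile(ta, 0.05), 0.01)
  init <- stats::setNames(rep(NA_real_, nrow(pt)), pt$name)
  init["a"] <- 2.5
  init["g"] <- 3
  if ("ta_min" %in% names(init)) init["ta_min"] <- ta_min0

  half_cross <- function(x, y, mid, decreasing = FALSE) {
    # log-interpolated abscissa where mean response crosses mid
    o <- order(x)
    x <- x[o]; y <- y[o]
    if (decreasing) { x <- rev(x); y <- rev(y) }
    above <- y >= mid
    i <- which(above)[1]
    if (is.na(i) || i == 1L) return(exp(mean(log(range(x)))))
    lx <- log(x[c(i - 1L, i)]); ly <- y[c(i - 1L, i)]
    exp(lx[1] + (mid - ly[1]) * diff(lx) / diff(ly))
  }

  f_hm0 <- p_e0 <- stats::setNames(numeric(length(durations)),
                                   as.character(durations))
  for (j in seq_along(durations)) {
    d <- durations[j]
    sub <- obs[abs(obs$train_duration_s - d) < 1e-9, ]
    ta_max0 <- min(max(stats::quantile(sub$time_allocation, 0.9), ta_min0 + 0.2), 1)
    mid <- (ta_min0 + ta_max0) / 2
    fsub <- if ("sweep_type" %in% names(sub) && any(sub$sweep_type == "frequency"))
      sub[sub$sweep_type == "frequency", ] else sub
    agg <- stats::aggregate(time_allocation ~ pulse_frequency_pps, fsub, mean)
    f_hm0[j] <- half_cross(agg$pulse_frequency_pps, agg$time_allocation, mid)
    psub <- if ("sweep_type" %in% names(sub) && any(sub$sweep_type == "price"))
      sub[sub$sweep_type == "price", ] else sub
    agg <- stats::aggregate(time_allocation ~ price_s, psub, mean)
    p_e0[j] <- half_cross(agg$price_s, agg$time_allocation, mid, decreasing = TRUE)
    nm <- par_name("ta_max", d)
    if (nm %in% names(init)) init[nm] <- ta_max0
    if ("ta_max" %in% names(init)) init["ta_max"] <- ta_max0
    nm <- par_name("f_hm", d)
    if (nm %in% names(init)) init[nm] <- f_hm0[j]
    nm <- par_name("p_e", d)
    if (nm %in% names(init)) init[nm] <- p_e0[j]
  }
  if (spec$model == "dual") {
    d_long <- max(durations)
    ffhm_long <- frequency_following(f_hm0[as.character(d_long)], tp$ff)
    init["chronaxie1"] <- 0.3
    init["chronaxie2"] <- min(3, spec$chronaxie_max)
    init["rheobase1"] <- ffhm_long / (1 + 0.3 / d_long)
    init["rheobase2"] <- ffhm_long / (1 + init[["chronaxie2"]] / d_long)
    init["w"] <- 0.6
    init["price_scale"] <- subjective_price(p_e0[as.character(d_long)], tp$sp)
  }
  pmin(pmax(init, pt$lower * 1.0000001), pt$upper * 0.9999999)
}

#' Fit a reward-mountain surface jointly across train durations
#'
#' Minimises the summed squared residuals between observed time
#' allocations and the model surface over all observations of both train
#' durations at once, honouring the shared/per-duration parameter
#' partition, box bounds, and fixed assignments of the [fit_spec()].
#' Positive parameters are optimised on the log scale and reported in
#' natural units. Optimisation is Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) from multiple seeded, jittered initial points
#' around data-driven guesses (the frequency sweep's half-rise and the
#' price sweep's half-fall); the best converged start wins, ties broken by
#' lexicographically smallest parameter vector. For the dual model,
#' integrators are relabelled so that `chronaxie1 <= chronaxie2`.
#'
#' @param observations Observation table with columns `train_duration_s`,
#'   `pulse_frequency_pps`, `price_s`, `time_allocation` (and ideally
#'   `sweep_type` for the data-driven initialisation).
#' @param spec A [fit_spec()].
#' @param tp A `transform_params` bundle.
#' @param seed Integer seed for the start jitter.
#' @param start Optional named vector of natural-unit starting values
#'   (overrides the data-driven guess; used for warm starts).
#' @return An object of class `mountain_fit`: natural-unit `estimates`,
#'   `objective` (residual sum of squares), `converged`, `degenerate`,
#'   `active_bounds`, `n_obs`, plus the spec and durations.
#' @export
fit_mountain <- function(observations, spec, tp = transform_params(),
                         seed = 1L, start = NULL) {
  stopifnot(inherits(spec, "fit_spec"), inherits(tp, "transform_params"))
  req <- c("train_duration_s", "pulse_frequency_pps", "price_s", "time_allocation")
  if (!all(req %in% names(observations)))
    stop("observations lack required columns: ",
         paste(setdiff(req, names(observations)), collapse = ", "), call. = FALSE)
  obs <- observations
  durations <- sort(unique(obs$train_duration_s))
  pt <- build_par_table(spec, durations)
  free <- is.na(pt$fixed)
  if (!any(free)) stop("no free parameters in fit spec", call. = FALSE)
  degenerate <- stats::var(obs$time_allocation) < 1e-12

  di <- match(obs$train_duration_s, durations)
  ff_obs <- frequency_following(obs$pulse_frequency_pps, tp$ff)
  sp_obs <- subjective_price(obs$price_s, tp$sp)
  ta_obs <- obs$time_allocation

  resid_fn <- function(theta) {
    nat <- natural_params(theta, pt)
    eval_model_ta(nat, spec$model, di, durations, ff_obs, sp_obs, tp) - ta_obs
  }

  init_nat <- init_guess(obs, pt, spec, durations, tp)
  if (!is.null(start)) {
    common <- intersect(names(start), names(init_nat))
    init_nat[common] <- pmin(pmax(start[common], pt$lower * 1.0000001),
                             pt$upper * 0.9999999)
  }
  lower_t <- to_opt(pt$lower[free], pt$trans[free])
  upper_t <- to_opt(pt$upper[free], pt$trans[free])
  theta0 <- to_opt(init_nat[free], pt$trans[free])

  starts <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(spec$n_starts), function(k) {
      if (k == 1L) return(theta0)
      jit <- stats::runif(length(theta0), -0.3, 0.3)
      jit[pt$trans[free] == "id"] <-
        stats::runif(sum(pt$trans[free] == "id"), -0.05, 0.05)
      pmin(pmax(theta0 + jit, lower_t), upper_t)
    })
  })

  best <- NULL
  diagnostics <- character()
  for (th0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower_t, upper = upper_t,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = spec$maxiter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) e)
    if (inherits(res, "error")) { diagnostics <- c(diagnostics, conditionMessage(res)); next }
    if (!res$info %in% 1:3 || !is.finite(res$deviance)) {
      diagnostics <- c(diagnostics, paste0("info=", res$info)); next
    }
    if (is.null(best) || res$deviance < best$deviance - 1e-12) {
      best <- res
    } else if (res$deviance <= best$deviance + 1e-12) {
      # objective tie: lexicographically smallest parameter vector wins
      nz <- (res$par - best$par)[res$par != best$par]
      if (length(nz) && nz[1] < 0) best <- res
    }
  }
  if (is.null(best))
    stop("mountain fit failed to converge from any start: ",
         paste(utils::head(unique(diagnostics), 3), collapse = "; "),
         call. = FALSE)

  nat <- natural_params(best$par, pt)
  tol_active <- 1e-6
  active <- stats::setNames(rep(FALSE, nrow(pt)), pt$name)
  active[free] <- (best$par <= lower_t + tol_active) | (best$par >= upper_t - tol_active)

  if (spec$model == "dual" && nat[["chronaxie1"]] > nat[["chronaxie2"]]) {
    swap <- function(v, a, b) { tmp <- v[[a]]; v[[a]] <- v[[b]]; v[[b]] <- tmp; v }
    nat <- swap(nat, "chronaxie1", "chronaxie2")
    nat <- swap(nat, "rheobase1", "rheobase2")
    nat[["w"]] <- 1 - nat[["w"]]
    active <- swap(active, "chronaxie1", "chronaxie2")
    active <- swap(active, "rheobase1", "rheobase2")
  }

  structure(list(estimates = nat, objective = best$deviance,
                 converged = TRUE, degenerate = degenerate,
                 info = best$info, active_bounds = active,
                 n_obs = nrow(obs), n_free = sum(free),
                 spec = spec, durations = durations, par_table = pt),
            class = "mountain_fit")
}

#' @export
coef.mountain_fit <- function(object, ...) object$estimates

#' @export
print.mountain_fit <- function(x, ...) {
  cat(sprintf("Reward-mountain fit (%s-integrator), %d observations\n",
              x$spec$model, x$n_obs))
  cat(sprintf("RSS = %.5f, %d free parameters, converged: %s\n",
              x$objective, x$n_free, x$converged))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Rebuild a parameter object from a fit
#'
#' Converts a `mountain_fit`'s natural-unit estimates back into a
#' [single_mountain_params()] or [dual_mountain_params()] object so the
#' fitted surface can be evaluated, gridded, or probed for effective
#' location parameters.
#'
#' @param fit A `mountain_fit`.
#' @return A mountain parameter object.
#' @export
params_from_fit <- function(fit) {
  stopifnot(inherits(fit, "mountain_fit"))
  nat <- fit$estimates
  d <- fit$durations
  g1 <- function(base) {
    if (base %in% names(nat)) rep(nat[[base]], length(d))
    else vapply(d, function(x) nat[[par_name(base, x)]], numeric(1))
  }
  if (fit$spec$model == "single") {
    single_mountain_params(a = nat[["a"]], g = nat[["g"]],
                           ta_min = nat[["ta_min"]], durations = d,
                           f_hm = g1("f_hm"), p_e = g1("p_e"),
                           ta_max = g1("ta_max"))
  } else {
    dual_mountain_params(
      integrator1 = sd_params(nat[["rheobase1"]], nat[["chronaxie1"]]),
      integrator2 = sd_params(nat[["rheobase2"]], nat[["chronaxie2"]]),
      w = nat[["w"]], price_scale = nat[["price_scale"]],
      a = nat[["a"]], g = nat[["g"]], ta_min = nat[["ta_min"]],
      durations = d, ta_max = g1("ta_max"))
  }
}

#' Percentile confidence interval by the order-statistic rule
#'
#' The interval spanned by the resample estimates after excluding the
#' lowest and highest `ceiling((1-level)/2 * B)` of them (25 per tail for
#' `B = 1000` at the 95% level). Endpoints are order statistics of the
#' estimate multiset; no interpolation.
#'
#' @param x Numeric vector of B resample estimates.
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
boot_percentile_ci <- function(x, level = 0.95) {
  B <- length(x)
  # round away float fuzz (0.025 * 200 = 5 + 9e-16) before taking the ceiling
  k <- ceiling(round((1 - level) / 2 * B, 9))
  if (B < 2 * k + 1) stop("too few resamples for the requested level", call. = FALSE)
  s <- sort(x)
  c(lower = s[k + 1L], upper = s[B - k])
}

#' Case-resampling bootstrap of a mountain fit
#'
#' Draws, independently at every design point (duration x sweep x
#' frequency x price), `n` observations with replacement from that
#' point's `n` observations — so per-point sample sizes are conserved
#' exactly — refits the surface jointly across durations, and collects
#' the estimates. Resample fits that fail are redrawn (with a logged
#' count); the run aborts if the failure rate exceeds `max_failure_rate`.
#' Refits warm-start at the full-data estimates with a single start,
#' keeping each refit cheap and deterministic under `seed`.
#'
#' @param observations Observation table (see [fit_mountain()]).
#' @param spec A [fit_spec()].
#' @param tp A `transform_params` bundle.
#' @param B Number of bootstrap resamples, default 1000.
#' @param seed Integer root seed.
#' @param max_failure_rate Abort threshold on redrawn fits, default 0.2.
#' @return An object of class `mountain_boot`: `estimates` (B x P tibble),
#'   `summary` (per-parameter mean and percentile CI), the full-data
#'   `fit`, `B`, `seed`, and `n_redrawn`.
#' @export
bootstrap_fit <- function(observations, spec, tp = transform_params(),
                          B = 1000, seed = 1L, max_failure_rate = 0.2) {
  full <- fit_mountain(observations, spec, tp, seed = seed)
  obs <- observations
  sweep_key <- if ("sweep_type" %in% names(obs)) obs$sweep_type else ""
  key <- paste(obs$train_duration_s, sweep_key,
               signif(obs$pulse_frequency_pps, 10), signif(obs$price_s, 10))
  groups <- split(seq_len(nrow(obs)), key)
  boot_spec <- spec
  boot_spec$n_starts <- 1L

  est <- matrix(NA_real_, nrow = B, ncol = length(full$estimates),
                dimnames = list(NULL, names(full$estimates)))
  n_redrawn <- 0L
  max_fail <- ceiling(max_failure_rate * B)
  draw <- 0L
  b <- 1L
  while (b <= B) {
    draw <- draw + 1L
    idx <- withr::with_seed(child_seed(seed, draw), {
      unlist(lapply(groups, function(gi)
        gi[sample.int(length(gi), length(gi), replace = TRUE)]),
        use.names = FALSE)
    })
    fit_b <- tryCatch(
      fit_mountain(obs[idx, ], boot_spec, tp, seed = seed,
                   start = full$estimates),
      error = function(e) e)
    if (inherits(fit_b, "error")) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_fail)
        stop("bootstrap aborted: ", n_redrawn, " resample fits failed (",
             conditionMessage(fit_b), ")", call. = FALSE)
      next
    }
    est[b, ] <- fit_b$estimates[colnames(est)]
    b <- b + 1L
  }

  free_names <- names(full$estimates)[is.na(full$par_table$fixed)]
  summ <- dplyr::bind_rows(lapply(free_names, function(nm) {
    ci <- boot_percentile_ci(est[, nm])
    tibble::tibble(parameter = nm, mean = mean(est[, nm]),
                   lower = ci[["lower"]], upper = ci[["upper"]])
  }))
  structure(list(estimates = tibble::as_tibble(as.data.frame(est)),
                 summary = summ, fit = full, B = as.integer(B),
                 seed = as.integer(seed), n_redrawn = n_redrawn,
                 durations = full$durations, spec = spec),
            class = "mountain_boot")
}

#' Bootstrap inference on duration-induced location shifts
#'
#' For each location parameter, computes the per-resample difference
#' between the long and short train-duration estimates (pairing by
#' resample index: both come from the same joint fit of each resample),
#' and reports the median difference, the 2.5/97.5 percentile confidence
#' interval by the order-statistic rule, and a significance flag raised
#' when that interval excludes 0. The secondary criterion — non-overlap of
#' the two durations' own 95% regions — is reported alongside. The sign
#' convention is long minus short, so the predicted frequency effect of
#' lengthening the train is a negative `f_hm` shift.
#'
#' @param boot A `mountain_boot` from a joint two-duration fit.
#' @param parameters Parameter bases to difference, default
#'   `c("f_hm", "p_e", "ta_max")` (for dual fits, only per-duration bases
#'   are available).
#' @param level Confidence level, default 0.95.
#' @return A tibble with one row per parameter: `median_diff`, `lower`,
#'   `upper`, `significant`, `nonoverlap`.
#' @export
shift_inference <- function(boot, parameters = c("f_hm", "p_e", "ta_max"),
                            level = 0.95) {
  stopifnot(inherits(boot, "mountain_boot"))
  if (length(boot$durations) != 2L)
    stop("shift inference needs exactly two train durations", call. = FALSE)
  d_short <- min(boot$durations)
  d_long <- max(boot$durations)
  est <- boot$estimates
  out <- lapply(parameters, function(base) {
    nm_s <- par_name(base, d_short)
    nm_l <- par_name(base, d_long)
    if (!nm_s %in% names(est) || !nm_l %in% names(est)) return(NULL)
    diffs <- est[[nm_l]] - est[[nm_s]]
    ci <- boot_percentile_ci(diffs, level)
    ci_s <- boot_percentile_ci(est[[nm_s]], level)
    ci_l <- boot_percentile_ci(est[[nm_l]], level)
    tibble::tibble(parameter = base,
                   short = d_short, long = d_long,
                   median_diff = stats::median(diffs),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   significant = ci[["lower"]] > 0 | ci[["upper"]] < 0,
                   nonoverlap = ci_s[["upper"]] < ci_l[["lower"]] |
                     ci_l[["upper"]] < ci_s[["lower"]])
  })
  res <- dplyr::bind_rows(out)
  attr(res, "sign_convention") <- "long_minus_short"
  res
}

#' Information-criterion comparison of fitted surfaces
#'
#' Gaussian-likelihood AIC and BIC from the residual sums of squares of
#' competing fits to the same observations (a variance parameter is
#' counted in addition to the surface parameters). Lower values indicate
#' the preferred model. Non-converged fits are excluded with a warning.
#'
#' @param observations The observation table both models were fitted to.
#' @param fits Named list of `mountain_fit` objects.
#' @return A tibble with `model`, `rss`, `n_par`, `aic`, `bic`,
#'   `delta_aic`, `delta_bic` (differences from the best), ordered best
#'   BIC first.
#' @export
compare_models <- function(observations, fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok)) {
    warning("excluding non-converged fits: ",
            paste(names(fits)[!ok], collapse = ", "))
    fits <- fits[ok]
  }
  n <- nrow(observations)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (f$n_obs != n)
      stop("fit '", nm, "' was not fitted to these observations", call. = FALSE)
    k <- f$n_free + 1L  # + residual variance
    ll <- -n / 2 * (log(2 * pi) + log(f$objective / n) + 1)
    tibble::tibble(model = nm, rss = f$objective, n_par = f$n_free,
                   aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k)
  })
  out <- dplyr::bind_rows(rows)
  out$delta_aic <- out$aic - min(out$aic)
  out$delta_bic <- out$bic - min(out$bic)
  out[order(out$bic), ]
}
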