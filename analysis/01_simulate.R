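#!/usr/bin/env Rscript

# Stage 1: build the survey design and simulate two synthetic subjects.
#
# Both subjects are probed with the full design: six 9-point pseudo-sweeps
# (frequency, price, radial; one set per train duration, 0.25 s and 1 s),
# 8 surveys, central points sampled twice per survey (16 replicates),
# extremes once (8 replicates).
#
#  * "uniform-substrate": a single-integrator ground truth whose f_hm obeys
#    the strength-duration law across durations while p_e stays put — the
#    behaviour expected of a homogeneous reward substrate.
#  * "dual-substrate": a dual-integrator ground truth whose long-chronaxie
#    integrator demands firing above the frequency-following plateau at the
#    short duration, producing the rightward price shift at the long
#    duration.

suppressPackageStartupMessages(library(rewardmountain))

seed <- 20260928L
tp <- transform_params()
dir.create("results", showWarnings = FALSE)

single_truth <- single_mountain_params(
  a = 3, g = 4, ta_min = 0.1, durations = c(0.25, 1),
  f_hm = c(200, 100),       # chronaxie 0.5 s: (1 + 4C)/(1 + C) = 2
  p_e = c(8, 8), ta_max = c(0.9, 0.85))

dual_truth <- dual_mountain_params(
  integrator1 = sd_params(rheobase = 50, chronaxie = 0.15),
  integrator2 = sd_params(rheobase = 40, chronaxie = 5),
  w = 0.6, price_scale = subjective_price(8, tp$sp),
  a = 3, g = 4, ta_min = 0.1, durations = c(0.25, 1),
  ta_max = c(0.9, 0.85))

centers <- function(par) {
  lapply(c(0.25, 1), function(d) {
    if (inherits(par, "single_mountain_params")) {
      i <- which(par$durations == d)
      list(f_hm = par$f_hm[i], p_e = par$p_e[i])
    } else {
      el <- effective_location_params(par, d, tp)
      list(f_hm = el$f_hm_effective, p_e = el$p_e_effective)
    }
  })
}

simulate_subject <- function(par, label, seed_offset) {
  ctr <- centers(par)
  sweeps <- c(build_pseudo_sweeps(ctr[[1]], 0.25, tp = tp),
              build_pseudo_sweeps(ctr[[2]], 1, tp = tp))
  sched <- build_survey_schedule(sweeps, n_surveys = 8,
                                 seed = seed + seed_offset)
  truth <- ground_truth(par, tp, noise_concentration = 30, subject = label)
  simulate_observations(truth, sched, seed = seed + seed_offset + 1L)
}

obs_single <- simulate_subject(single_truth, "uniform-substrate", 0L)
obs_dual <- simulate_subject(dual_truth, "dual-substrate", 100L)

write_observations(obs_single, "results/observations_uniform.csv")
write_observations(obs_dual, "results/observations_dual.csv")

obs <- rbind(obs_single, obs_dual)
cat(sprintf("simulated %d observations (%d per subject), TA range %.3f-%.3f\n",
            nrow(obs), nrow(obs_single),
            min(obs$time_allocation), max(obs$time_allocation)))
counts <- table(paste(obs_single$sweep_type, obs_single$train_duration_s))
cat("trials per sweep x duration (uniform-substrate):\n")
print(counts)

manifest <- run_manifest(list(stage = "simulate", seed = seed,
                              noise_concentration = 30, n_surveys = 8),
                         seed = seed)
cat(sprintf("config hash %s, package %s\n",
            manifest$config_hash, manifest$package_version))
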