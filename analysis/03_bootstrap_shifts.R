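#!/usr/bin/env Rscript

# Stage 3: case-resampling bootstrap of the joint fit for each subject and
# shift inference on the location parameters. Resamples are drawn with
# replacement within each design point (preserving the 8/16 replicate
# structure), the surface is refitted jointly per resample, and the
# long - short differences are summarised by their median and 2.5/97.5
# percentile interval (order statistics). B is scaled to 200 resamples
# here to keep the stage interactive; the inferential rule is identical
# at any B.

suppressPackageStartupMessages(library(rewardmountain))

tp <- transform_params()
B <- 200
spec <- fit_spec("single")
files <- c(`uniform-substrate` = "results/observations_uniform.csv",
           `dual-substrate` = "results/observations_dual.csv")

shifts <- list()
fits <- list()
for (subj in names(files)) {
  obs <- read_observations(files[[subj]], durations = c(0.25, 1))
  bt <- bootstrap_fit(obs, spec, tp, B = B, seed = 33)
  fits[[subj]] <- bt$fit
  shifts[[subj]] <- shift_inference(bt, parameters = c("f_hm", "p_e", "ta_max"))
  cat("\n==", subj, "(", B, "resamples,", bt$n_redrawn, "redrawn ) ==\n")
  print(shifts[[subj]])
}

report <- assemble_shift_report(shifts, fits)
readr::write_csv(report, "results/shift_report.csv")
cat("\nwrote results/shift_report.csv\n")
cat("Shifts are long (1 s) minus short (0.25 s); a '*' marks a 95%\n",
    "percentile interval excluding zero. Expected pattern: a starred\n",
    "negative f_hm shift in both subjects (strength-duration effect), and\n",
    "a starred positive p_e shift only in the dual-substrate subject\n",
    "(integrator dropout at the short duration).\n", sep = "")
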