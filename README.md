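# rewardmountain

Fitting and probing the **reward-mountain model** of brain stimulation
reward: the 3D surface relating the time a subject allocates to working for
rewarding electrical stimulation to the stimulation's pulse frequency and
its price (the cumulative lever-hold time required per reward).

The package is aimed at behavioural neuroscientists analysing intracranial
self-stimulation experiments run under a cumulative handling-time schedule,
and at anyone who needs a tested reference implementation of the model's
extended and dual-integrator forms for simulation studies.

## The model

Time allocation (TA) follows a matching-law surface over pulse frequency
*F* and price *P* at train duration *D*:

```
TA = (TAmax − TAmin) · U^a / (U^a + (SP/SPe)^a) + TAmin
U  = FF^g / (FF^g + FFhm^g)
```

with two fixed psychophysical maps feeding it:

* subjective price `SP = SPmin + SPbend·ln(1 + exp((P − SPmin)/SPbend))`
  (SPmin = 1.75 s, SPbend = 0.57 s);
* frequency following
  `FF = Fbend·[ln(1+exp(FNearMax/Fbend)) − ln(1+exp((FNearMax−F)/Fbend))]`
  (Fbend = 20.63 pps, FNearMax = 342.9 pps), which saturates at a plateau of
  about **343 spikes/s**.

The half-maximal firing requirement obeys the strength–duration law
`FFhm(D) = rheobase·(1 + chronaxie/D)`, so lengthening the train shifts the
mountain to lower pulse frequencies. A dual-integrator variant pools two
strength–duration-governed intensity functions with weights `w` and `1 − w`;
when one integrator's demand at a short duration exceeds the
frequency-following plateau it drops out, which *also* moves the mountain
along the price axis — the diagnostic the model exists to test.

The toolchain around the surfaces: computation of TA from time-stamped
lever-event streams (tap rule, blackout and pre-first-reward exclusions),
the pseudo-sweep survey design generator with a synthetic operant-session
simulator, joint nonlinear least-squares fitting across train durations,
case-resampling bootstrap with order-statistic percentile intervals, shift
inference, and AIC/BIC model comparison.

## Worked example

```r
library(rewardmountain)
tp <- transform_params()

# ground truth: f_hm halves from 0.25 s to 1 s (chronaxie 0.5 s), p_e fixed
truth <- single_mountain_params(a = 3, g = 4, ta_min = 0.1,
                                durations = c(0.25, 1),
                                f_hm = c(200, 100), p_e = c(8, 8),
                                ta_max = c(0.9, 0.85))

# the study design: 6 nine-point pseudo-sweeps, 8 surveys, 8/16 replicates
sweeps <- c(build_pseudo_sweeps(list(f_hm = 200, p_e = 8), 0.25, tp = tp),
            build_pseudo_sweeps(list(f_hm = 100, p_e = 8), 1, tp = tp))
sched <- build_survey_schedule(sweeps, n_surveys = 8, seed = 42)
obs <- simulate_observations(ground_truth(truth, tp, noise_concentration = 30),
                             sched, seed = 7)

fit <- fit_mountain(obs, fit_spec("single"), tp, seed = 1)
print(fit)
#> Reward-mountain fit (single-integrator), 672 observations
#> RSS = 3.20544, 9 free parameters, converged: TRUE
#>           a           g      ta_min   f_hm_0.25      f_hm_1    p_e_0.25
#>      2.8684      4.0194      0.0973    201.3670    103.5353      7.9558
#>       p_e_1 ta_max_0.25    ta_max_1
#>      8.0368      0.9062      0.8614

bt <- bootstrap_fit(obs, fit_spec("single"), tp, B = 200, seed = 3)
shift_inference(bt, parameters = c("f_hm", "p_e"))
#> # A tibble: 2 × 8
#>   parameter short  long median_diff    lower   upper significant nonoverlap
#>   <chr>     <dbl> <dbl>       <dbl>    <dbl>   <dbl> <lgl>       <lgl>
#> 1 f_hm       0.25     1    -97.8    -115.    -87.9   TRUE        TRUE
#> 2 p_e        0.25     1      0.0636   -0.787   0.858 FALSE       FALSE
```

Reading the output: the fit recovers the generating surface (half-maximal
pulse frequency ≈ 201 pps at 0.25 s and ≈ 104 pps at 1 s against a truth of
200/100; half-fall price ≈ 8.0 s against 8 s). The bootstrap shift table
differences the 1 s and 0.25 s estimates within each of 200 joint resample
fits: the pulse-frequency location drops by ≈ 98 pps with a 95% percentile
interval excluding zero (a reliable, predicted shift), while the price
location does not move (interval spans zero), as a single, homogeneous
integrator predicts.

The `analysis/` directory walks the full pipeline as numbered stages —
simulate, fit, bootstrap shifts, dual-integrator mechanism and model
comparison, event-level validation — writing tables under `results/`.

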