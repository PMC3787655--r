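---
title: "Methods: the reward-mountain model, its extensions, and the bootstrap pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the reward-mountain model, its extensions, and the bootstrap pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Intracranial self-stimulation under a cumulative handling-time schedule
confronts a rat with a stream of trials, each offering stimulation trains of a
fixed pulse frequency $F$ at a fixed price $P$ (the cumulative lever-hold time
required per reward) and a fixed train duration $D$. The dependent measure is
time allocation (TA): the proportion of corrected trial time spent working.
The reward-mountain model describes TA as a 3D surface over $(F, P)$:

$$
TA = (TA_{max} - TA_{min})\,
\frac{U^a}{U^a + (SP/SP_e)^a} + TA_{min},
\qquad
U = \frac{FF^g}{FF^g + FF_{hm}^g}
$$

`time_allocation_extended()` implements this surface. $U$ is the reward
intensity produced by the induced firing frequency $FF$, rising
logistically (in log coordinates) with growth exponent $g$ around the
half-maximal requirement $FF_{hm}$; the matching-law stage converts the
payoff ratio — intensity over relative subjective price — into time
allocation with payoff-sensitivity exponent $a$ between the floor
$TA_{min}$ and ceiling $TA_{max}$. Two psychophysical maps connect the
experimenter's variables to the model's internal ones:

* **Subjective price** (`subjective_price()`):
  $SP = SP_{min} + SP_{bend}\,\ln(1 + e^{(P - SP_{min})/SP_{bend}})$, a
  softplus with floor $SP_{min} = 1.75$ s and bend $SP_{bend} = 0.57$ s. Very
  cheap rewards all feel about equally cheap; beyond a few bend-widths the map
  is the identity. With these constants the relative gap to the identity is
  about 0.27% at $P = 4$ s and falls below 0.2% just above it, so we treat
  "negligible above roughly 4 s" as qualitative, not as an exact threshold.
* **Frequency following** (`frequency_following()`):
  $FF = F_{bend}[\ln(1+e^{F_{NearMax}/F_{bend}}) - \ln(1+e^{(F_{NearMax}-F)/F_{bend}})]$
  with $F_{bend} = 20.63$ pps and $F_{NearMax} = 342.9$ pps: one spike per
  pulse at moderate frequencies, saturating at a plateau of
  $F_{bend}\ln(1+e^{F_{NearMax}/F_{bend}}) \approx 343$ spikes/s. The directly
  stimulated neurons cannot be driven faster no matter the pulse rate.

Both constants ship as defaults of `sp_params()` / `ff_params()` and are
treated as known (they come from separate psychophysical experiments); the
package does not estimate them.

The legacy surface (`time_allocation_original()`) is the same expression with
$SP \equiv P$ and $FF \equiv F$.

## Train duration and the strength-duration law

The firing frequency needed for a half-maximal reward falls hyperbolically
with train duration (`half_max_firing_at_duration()`):

$$ FF_{hm}(D) = FF_{hmR}\left(1 + \frac{C}{D}\right), $$

with rheobase $FF_{hmR}$ (the demand at infinitely long trains) and chronaxie
$C$ (the duration at which the demand doubles). Lengthening the train from
0.25 s to 1 s therefore shifts the mountain toward lower pulse frequencies by
the factor $(1+4C)/(1+C)$, while — under a single integrator — leaving the
price-axis location $P_e$ untouched: that is the testable pair of predictions
the pipeline is built around.

## The dual-integrator variant

`time_allocation_dual()` relaxes the homogeneous-substrate assumption: two
integrators with separate strength-duration laws and maximum-intensity
weights $w$ and $1-w$ are pooled,

$$ I(FF, D) = w\,u_1 + (1-w)\,u_2, \qquad
   u_i = \frac{FF^g}{FF^g + FF_{hm,i}(D)^g}, $$

and enter the matching law through the payoff $V = I \cdot s / SP$, where the
payoff scale $s$ (`price_scale`) is the subjective price at which a
unit-maximal reward yields unit payoff. This parameterisation was a genuinely
open design choice: we use a single scale shared across durations because it
is minimal and reduces *algebraically* to the single-integrator surface when
$w = 1$ and $s = SP_e$ (the reduction is verified to 1e-9 on a 50×50 grid in
the tests). The payoff stage is isolated in one internal function
(`dual_log_payoff()`) so an alternative bookkeeping — e.g. per-duration
scales — is a one-line swap.

The mechanism of interest: when $FF_{hm,2}(0.25\,\mathrm{s})$ exceeds the
~343 spikes/s frequency-following plateau, integrator 2 cannot be driven
appreciably at any attainable pulse frequency. Maximum achievable intensity
collapses toward $w$, and the price at which the animal still allocates
halfway for the best available reward drops. At 1 s the integrator
re-engages and the price location moves right — a duration-induced $P_e$
shift that the single-integrator model forbids. Because the dual surface's
location is an emergent property, it is reported through
`effective_location_params()`: the pulse frequency at which intensity reaches
half its *achievable* maximum, and the objective price at which TA for the
maximal achievable reward is halfway between floor and ceiling. For a
single-integrator surface these coincide with the stored $F_{hm}$/$P_e$
whenever plateau saturation is essentially complete.

# Numerical choices

* Both softplus expressions are evaluated as
  $\ln(1+e^x) = \max(x, 0) + \ln(1+e^{-|x|})$; the printed forms overflow for
  realistic arguments (e.g. a price of a few hundred seconds).
* The inverse maps (`objective_price_from_subjective()`,
  `pulse_frequency_for_firing()`) use the exact closed-form softplus inverse
  $\mathrm{softplus}^{-1}(s) = \ln(e^s - 1)$, stabilised as
  $s + \ln(-\mathrm{expm1}(-s))$, rather than iterative root finding: both
  forward maps are softplus-affine, so the inverse is available in closed
  form and round-trips at machine precision. Firing demands at or above the
  plateau return a tagged *unreachable* value, not an error — the
  integrator-dropout regime is meaningful, not exceptional.
* Intensity ratios and matching-law powers are computed in log space via
  `plogis` ($x^a/(x^a + y^a) = \mathrm{logit}^{-1}(a(\ln x - \ln y))$), so
  large fitted exponents cannot overflow.
* In `compute_time_allocation()`, release gaps of exactly the 1 s tap
  threshold count as non-work (the inclusion rule is *strictly* less than
  1 s); the span before the first reward is removed from numerator and
  denominator alike; blackouts are reconstructed as
  $[t_{reward}, t_{reward} + 2\,\mathrm{s}]$; a release gap spanning a reward
  is classified by its total length; trials that never earn a reward return a
  tagged undefined value and are excluded from fitting.

# The synthetic-data generator

No raw subject data accompany the behavioural design, so the package's
generator *is* the study bench. It reproduces the design exactly: three
pseudo-sweeps per duration — nine points, equally spaced along a straight
line in (log F, log P); the frequency sweep at constant low price, the price
sweep at constant high frequency, the radial sweep running diagonally through
the location point $(F_{hm}, P_e)$ — pooled into a per-survey urn in which
each sweep's five central points appear twice and its four extremes once,
drawn without replacement in seeded random order. Eight surveys give 16
replicates per central point and 8 per extreme, 672 observations per subject.

Generator conditions are fixed, not tuned:

* **Train durations** 0.25 s and 1 s; **8 surveys**; **8/16 replicates** —
  the study design.
* **Noise**: TA is a bounded proportion and no noise law is prescribed, so
  observations are beta-distributed about the surface with concentration
  $\phi = 30$ (SD $\approx$ 0.09 at mid-range allocations), chosen once as
  representative of well-trained operant performance; `Inf` gives noiseless
  data. An optional heteroscedastic flag halves the concentration on the
  surface's rising portion, where non-asymptotic performance is expected to
  be more variable; it defaults to off.
* **Sweep anchors**: the design prescribes only a "low" price and "high"
  frequency for the axis-parallel sweeps; defaults are twice the
  subjective-price floor (3.5 s) and 90% of $F_{NearMax}$ (~309 pps),
  both configurable via `sweep_spans()`.
* **Ground-truth locations**: `f_hm` = 200/100 pps across 0.25/1 s (a
  chronaxie of 0.5 s via the strength-duration ratio), `p_e` = 8 s at both
  durations, $a = 3$, $g = 4$, floors/ceilings 0.1 and 0.9/0.85 — magnitudes
  in the range reported for well-placed electrodes.

`simulate_trial_events()` additionally emits raw lever streams: a two-state
work/leisure alternating-renewal process with exponential dwell times
(mean work bout 12 s; leisure mean set so the stationary work fraction equals
the surface TA; starts drawn from the stationary distribution, which
exponential memorylessness makes exact), trial length sized for 25 rewards,
2 s blackouts after each reward, and each test trial flanked by leading and
trailing bracket trials. What the generator does *not* emulate: satiation or
drift within sessions, motoric side-effects at high frequencies, priming
carry-over, or serially correlated bout structure. Passing tests therefore
demonstrate correctness of the pipeline under the stated design and a
plausible noise law — not robustness to every pathology of real rats.

# Fitting and inference

`fit_mountain()` minimises summed squared TA residuals over all observations
of both durations jointly (Levenberg-Marquardt with box bounds via
minpack.lm). Only $F_{hm}$, $P_e$ and $TA_{max}$ take per-duration values;
$a$, $g$, $TA_{min}$ are shared. Residuals are unweighted: resampling happens
at the design-point level with fixed per-point $n$, which makes unweighted
and point-weighted losses nearly equivalent in expectation, and no weighting
scheme is prescribed. Location parameters are optimised on the log scale and
reported in natural units. Starts: a data-driven guess (half-rise of the
frequency sweep, half-fall of the price sweep, TA quantiles for floor and
ceiling) plus seeded log-uniform jitters (default 8 starts); best converged
objective wins, exact ties broken by the lexicographically smallest
parameter vector. The constrained dual fit fixes $a$, $g$, $TA_{min}$,
$TA_{max}$ (as done when the data cannot support them) and caps both
chronaxies at 6 s; integrators are relabelled so $C_1 \le C_2$, removing
label switching. Under noise the pair ($w$, payoff scale) trades off along a
ridge — expected with only two durations — while the effective locations
remain identified; the noiseless fit recovers all generating parameters.

`bootstrap_fit()` draws, independently at every design point, $n$
observations with replacement from that point's $n$ observations (8 stays 8,
16 stays 16), refits jointly per resample — warm-started at the full-data
estimates with a single start — and summarises each parameter by the mean of
the $B$ estimates and the percentile interval that drops the
$\lceil 0.025B \rceil$ smallest and largest estimates (25 per tail at
$B = 1000$; endpoints are order statistics, never interpolated). Failed
resample fits are redrawn with a logged count, aborting if more than 20% of
draws fail. `shift_inference()` differences the long- and short-duration
estimates *within* each resample (they come from one joint fit), reports the
median difference and its percentile interval, flags significance when the
interval excludes zero, and also reports the secondary non-overlap criterion
on the two parameters' own intervals. The sign convention is long minus
short, so the predicted frequency effect is a negative $F_{hm}$ shift.
`compare_models()` converts residual sums of squares into Gaussian
AIC/BIC (counting a variance parameter); lower is better.

## Problem sizes used in validation

The test-suite simulations run at the full study design (672 observations
per synthetic subject). Calibration of the null rate of the shift test uses
100 replicate experiments at $B = 200$ — the percentile rule is identical at
any $B$, and 200 resamples give tail order statistics (6th/195th) adequate
for a calibration count — and power uses 20 experiments at a
strength-duration-consistent halving of $F_{hm}$. Parameter-recovery checks
use 20 replicate experiments at the study noise and again noiseless. The
analysis drivers under `analysis/` use $B = 200$ for the same reason.

# Known limitations

* With two train durations the dual model's five structural parameters are
  not separately identified under realistic noise (the package makes this
  visible through `effective_location_params()` rather than hiding it);
  chronaxie/rheobase estimation proper needs more durations, including one
  near the rheobase regime.
* The percentile bootstrap is the prescribed inferential rule; no BCa or
  studentised variants are offered.
* The beta noise law is an assumption of convenience for a bounded response;
  real TA distributions can be zero-inflated at the floor.
* Bracket trials are quality control only; they never enter fits. A bracket
  trial that earns no reward is scored as zero allocation in the stability
  report (the animal demonstrably did not work), whereas rewardless *test*
  trials are treated as undefined and dropped.
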