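# faidsim

A desk-scale in-silico test bench for **fully automatic insulin delivery
(FAID)** in type 1 diabetes — closed-loop glucose control that never asks
the patient to announce meals or count carbohydrates.

People on hybrid closed-loop therapy still have to estimate the
carbohydrate content of every meal and announce it to the pump; the
announcement drives a feedforward bolus through
`u = CHO/CR + (BG - BG_T)/CF - IOB`. Misestimation (typically ~20%) and
the burden of counting are the weak points. faidsim implements and
evaluates the alternative: detect unannounced meals from CGM and insulin
data alone, and size the bolus with a learned policy instead of a
carbohydrate count.

The package provides, as composable R functions with a classed
`faid_policy` model object at the centre:

- **Virtual patient** — Bergman minimal-model ODEs
  (`dG/dt = -(p1 + X)G + p1*Gbl + D/Vg` plus remote insulin action,
  subcutaneous insulin and sensing compartments, and a two-compartment
  meal absorption chain), with circadian insulin-sensitivity variation,
  per-meal absorption randomness, CGM noise, meal scenario generation and
  reproducible synthetic cohorts (`patient_params()`, `make_cohort()`,
  `generate_scenario()`, `simulate_loop()`).
- **Controller** — PD law `u = kp[e + tau_d dG/dt] + ubl + ubolus` with
  `kp = 60 TDI/(tau_d 1500)`, insulin feedback, and a sliding-mode SAFE
  layer that raises the glucose reference to bound insulin-on-board.
- **Meal detector** — an unscented Kalman filter over the model augmented
  with a random-walk glucose-appearance disturbance `D(t)`; meals are
  flagged when the CGM/disturbance cross-covariance exceeds a threshold on
  three consecutive samples with rising glucose, outside the 23:00-06:00
  night window (`detector_init()`, `ukf_step()`, `meal_flag()`).
- **DRL bolus calculator** — 24 deep Q-networks per patient (3 meals x 8
  pre-meal glucose bands), each a 15-28-28-28-15 fully connected network
  over a 15-dimensional CGM-history state, trained by experience replay
  with target networks and an epsilon-greedy schedule; boluses pass a
  bolus-on-board safety adjustment (`drl_train()`, `predict()`,
  `simulate()`).
- **Baseline + metrics** — the standard bolus calculator with Gaussian
  carbohydrate misestimation, and consensus CGM outcomes (time in range,
  GMI, GRI, insulin totals) with paired Wilcoxon comparisons
  (`standard_bolus()`, `cgm_metrics()`, `run_arm()`, `compare_arms()`).

## Worked example

Train a bolus policy for one virtual patient at desk scale (a few minutes
on one CPU), then run a two-week unannounced-meal trial:

```r
library(faidsim)

p   <- patient_params()           # default adult: TDI 30 U, basal 0.23 U/h
pol <- drl_train(p, train_config(memory_days = 100, iterations = 300),
                 seed = 1, announced = FALSE)   # detector-in-loop training
summary(pol)

sim <- simulate(pol, seed = 7, days = 14, arm = "faid")
rep <- cgm_metrics(sim$trace)
rep[c("basal_per_day", "bolus_per_day", "tdi_per_day")] <-
  insulin_totals(sim$trace)
print(rep)
```

```
Training: 300 iterations
  daily hypoglycemia events, median: first decile 2.0 -> last decile 1.0
  mean per-meal reward: -51.4 -> -24.0
  replay memories: 1-173 experiences per active DQN
CGM: mean 136.7, median 122.6, CV 34.4%, GMI 6.58%
TIR 70-180: 79.7%  TBR <70: 2.0%  TAR >180: 18.3%  GRI 21.3
Insulin: basal 10.7 U/day, bolus 2.7 U/day, TDI 13.4 U
```

Reading this: random dosing early in training causes about two
hypoglycemic events per day; by the end the greedy policy has learned to
withhold or shrink boluses that the feedback controller would turn into
overdoses, and the deployed loop keeps ~80% of readings in 70-180 mg/dL
with 2.0% below 70 — the detector contributes its flags 30-40 min after
each meal, and the PD loop covers what the late bolus cannot. The mean
per-meal reward stays negative because a detection-delayed bolus cannot
prevent the postprandial peak (peaks above 200 mg/dL score negative even
without hypoglycemia).

The detector alone:

```r
Rscript inst/cli/faidsim.R calibrate-detector --days 4 --seed 1
#> highest_sensitivity  sens 100.0%  FP/day 0.00  median latency 30 min
#> trade_off            sens 62.5%  FP/day 0.00  median latency 41 min
#> lowest_fp            sens 31.2%  FP/day 0.00  median latency 46 min
```

(sensitivity over all meals including 30-50 g snacks, which trade-off
tuning deliberately half-suppresses; 60-80 g meals are detected at
>= 90% under trade-off tuning).

A command-line front end (`inst/cli/faidsim.R`) wraps training,
simulation, report generation and detector calibration; an annotated
experiment configuration ships at
`inst/extdata/example_experiment.yaml`.

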