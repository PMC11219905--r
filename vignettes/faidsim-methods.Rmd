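---
title: "Fully automatic insulin delivery in silico: models, controller, detector and bolus agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fully automatic insulin delivery in silico: models, controller, detector and bolus agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

faidsim is a desk-scale test bench for *fully automatic insulin delivery*
(FAID) in type 1 diabetes: a closed loop that never asks the patient to
announce meals or count carbohydrates. It couples four components, each of
which can also be used on its own:

1. a **virtual patient** (minimal-model glucose-insulin ODEs with meal
   absorption, circadian insulin sensitivity and CGM sensing);
2. a **PD controller** with insulin feedback (IFB) and a sliding-mode
   safety layer (SAFE) that bounds insulin on board (IOB);
3. an **unscented-Kalman-filter meal detector** that estimates an
   unmeasured glucose-appearance disturbance and flags unannounced meals;
4. a **deep-RL bolus calculator**: a bank of 24 small Q-networks
   (3 meals x 8 pre-meal glucose bands) trained by experience replay,
   which sizes the meal bolus from CGM history alone.

A standard bolus calculator (SBC) with carbohydrate misestimation serves as
the hybrid (meal-announcing) baseline, and a consensus CGM metrics module
(time in range, GMI, GRI, insulin totals, paired Wilcoxon comparisons)
scores every arm.

## The virtual patient

The plant is the Bergman minimal model with a subcutaneous sensing
compartment and a two-compartment subcutaneous insulin chain:

$$
\begin{aligned}
\dot G_{pl} &= -(p_1 + X)\,G_{pl} + p_1 G_{bl} + D(t)/V_g \\
\dot G_s &= (g_s G_{pl} - G_s)/\tau_s \\
\dot X &= -p_2 X + p_3 I \\
\dot I &= -k_f I + \tfrac{1000}{V_i}\,S_2/t_{maxI} \\
\dot S_1 &= u(t)/60 - S_1/t_{maxI}, \qquad
\dot S_2 = (S_1 - S_2)/t_{maxI}
\end{aligned}
$$

with glucose in mg/dL, insulin delivery $u$ in U/h, plasma insulin $I$ in
mU/L, and the meal disturbance $D(t)$ in mg/min. Plasma insulin is modelled
in absolute terms (not as a deviation from basal), so $G_{bl}$ is the
glucose asymptote at *zero* insulin and the basal infusion $u_{bl}$ places
the operating point below it; the model is initialised at the analytic
fixed point of the basal infusion, which makes the basal state an exact
equilibrium of both the plant and the closed loop.

Meals enter through a two-compartment absorption chain ($M_1, M_2$, time
constant `tmax_meal` = 40 min, bioavailability 0.8), giving
$D(t) = 0.8 \cdot 1000 \cdot M_2 / t_{max,meal}$. A per-meal log-normal
multiplier (CV 0.2) rescales the absorption rate; because the chain is
shared, a new meal's multiplier also applies to the residual tail of the
previous meal, an approximation that matters only for meals closer than
about two absorption time constants.

**Parameter calibration.** Defaults were fixed once against clinical
anchors: basal operating glucose about 120 mg/dL at the basal rate, a
1 U correction drop of roughly 30 mg/dL, a 60 g meal excursion of
100-160 mg/dL, and basal insulin near 6 U/day — all inside published adult
ranges for this model class. The `TDI` attribute is the patient's total
daily insulin *requirement* (basal plus full coverage of a nominal
210 g/day carbohydrate load, `insulin_requirement()`), because in a hybrid
closed loop much of the prandial insulin is delivered by the feedback
controller and the *delivered* total would understate the therapy scale
used for guideline parameters (CR = 500/TDI, CF = 1800/TDI) and the bolus
action grids. A single-potency minimal model cannot match the 500 and 1800
rules simultaneously at every operating point; the compromise is the
requirement-based TDI, and the residual mismatch (guideline corrections
are mildly conservative in this plant) is a known property of the bench.

Cohorts (`make_cohort()`) apply log-normal jitter (CV 15%) to the kinetic
parameters, re-solve the basal rate per patient for a 120 mg/dL operating
point, and recompute the TDI requirement; a master seed makes cohorts
reproducible.

**Intrapatient variability** follows the common in-silico protocol:
sinusoidal circadian modulation of insulin sensitivity
($p_3(t) = p_3(1 + a\sin 2\pi(t-\phi)/1440)$, default amplitude 0.2 with
the sensitivity minimum near 04:00), random meal absorption rates, random
CHO content, and additive i.i.d. Gaussian CGM noise (SD 2 mg/dL,
consistent with a MARD <= 10% sensor). White 5-min noise puts more energy
into the CGM derivative than a filtered real sensor would; the controller
compensates with a two-sample smoothed difference (below).

**What the generator does not emulate:** exercise, stress, medication,
sensor dropouts/drift, pump occlusions, and the full inter-patient
diversity of a clinical cohort. Passing tests therefore demonstrate
internal correctness and plausible closed-loop behaviour, not clinical
performance.

## Controller: PD + IFB + SAFE

The continuous channel is
$u = k_p\,[e + \tau_d\,\dot G] + u_{bl}$ with $e = CGM - G_{vref}$,
$k_p = 60\,TDI/(\tau_d \cdot 1500)$ U/h per mg/dL and $\tau_d = 90$ min.
$\dot G$ uses a two-sample backward difference ($\pm 10$ min), the smoothed
option of the two standard choices, because a one-sample difference of
white CGM noise rectifies through the non-negativity clamp into a net
insulin surplus. Insulin feedback subtracts
$\eta(\hat i_p - \hat i_{pss})$, where $\hat i_p$ is propagated online
through the nominal insulin sub-model; $\eta = 0.3$ U/h per mU/L was set
during calibration so that the feedback loop alone does not turn rectified
sensor noise into a chronic insulin surplus. The
continuous channel saturates at `pump_max` (6 U/h); boluses are
superimposed as one-step impulses.

The SAFE layer bounds the IOB estimate of the two-compartment model
$\dot c_1 = u - k_{dia} c_1$, $\dot c_2 = k_{dia}(c_1 - c_2)$,
$\widehat{IOB} = c_1 + c_2$ (integrated exactly over each step;
$k_{dia} = 0.025$/min gives ~4 h of insulin action). The sliding surface
$s = (\widehat{IOB} - \overline{IOB}) + \tau_{sm}\,d\widehat{IOB}/dt$ uses
a constant bound ($\overline{IOB}$ = 1.5 x hourly-basal x 4 h by default),
so the bound's derivative is zero. When $s > 0$ a switching signal
$\nu^+ = 100$ mg/dL is low-pass filtered ($\lambda = 1/20$ min$^{-1}$) onto
the reference, $G_{vref} = G_{ref} + \nu_f$, throttling the PD action until
IOB returns inside the invariant set. The layer gates only the continuous
channel; a bolus impulse can exceed the bound by at most its own size for
the step in which it lands.

## Meal detector

The detector runs an unscented Kalman filter over the same model equations
augmented with the disturbance state $D$ held as a random walk (process SD
30 mg/min per 5-min step). The detector's parameters are the *nominal*
defaults, not the jittered plant's — the realistic mismatched-model
regime. Scaled sigma points ($\alpha = 10^{-3}, \beta = 2, \kappa = 0$)
propagate through one RK4 step per 5-min sample (halving the substep
changes no detection on test traces); the CGM measurement is linear in the
state, so the measurement update is an exact Kalman step. Covariances are
re-symmetrised each step with escalating jitter on Cholesky failure.

The trigger statistic is the raw (1/m-normalised) cross-covariance between
the buffered CGM sequence and the forward difference of the disturbance
estimate over a 12-sample (60 min) window, maximised over lags 0..m-1
(the single-lag estimator is exposed as `cross_covariance()`). A meal is
flagged when the statistic met the threshold on three consecutive samples
(15 min), the disturbance increment and the 15-min CGM change are both
positive, the clock is outside the night window [23:00, 06:00), and a
2-h refractory hold-off has elapsed.

The three named tunings map to thresholds calibrated on synthetic traces
in this package (T = 100 / 300 / 500 for highest-sensitivity / trade-off /
lowest-FP at window 12): at trade-off tuning, 60-80 g meals are detected
with >= 90% sensitivity, zero-to-rare false positives and median latency
in the 30-40 min band, while 30-50 g snacks are detected substantially
less often — the size-selective pattern expected of this detector class. Because plant
and detector share model structure here, absolute sensitivity is
optimistic relative to a physiological simulator.

## The DRL bolus calculator

Each patient owns 24 Q-networks: one per meal (breakfast/lunch/dinner,
assigned by time-of-day bins [05,11)/[11,17)/[17,23)) and per pre-meal
glucose band (8 subaction spaces: >=200, [180,200), ..., [80,100), <80
mg/dL). Each network is fully connected 15-28-28-28-15 (three hidden
layers of 28 ReLU units): 15 state inputs, 15 action Q-values.

**State** (15 numbers): max and min CGM of the 4-h window before the
(detected) meal, the 12 samples of the last hour, and the area under the
curve outside [70, 180] mg/dL. The AUC integrates the absolute distance
from the violated bound sample-and-hold at 5 min (hypo- and hyperglycemic
excesses summed), so a constant 200 mg/dL window scores
20 x 240 = 4800 mg/dL.min. Glucose features are scaled by 1/180 and the
AUC by 1/1000 at the network input.

**Actions**: 15 bolus magnitudes per (meal, band): a power-curve grid from
0 to 1.8 x the guideline meal bolus (nominal meal CHO / CR), shifted up by
the guideline correction for the band midpoint above 120 mg/dL and scaled
down in the lowest band. The first action is always exactly 0 U — with a
30-40 min detection delay the feedback controller has often already
covered much of the meal, and withholding the bolus must remain available
to the agent. The grid is deliberately wide — its top is knowingly
excessive — so that the penalty structure, not the menu, shapes the
learned dose. The chosen bolus passes through the five-branch
bolus-on-board adjustment (subtraction above 180 mg/dL when the bolus
exceeds the on-board ratio; 5/10/20% reductions at lower glucose when it
does not), with the on-board estimate from a bolus-only two-compartment
model.

**Reward**: the 12-valued piecewise map on the postprandial extrema
(+50 for a window inside 70-180 mg/dL down to -80 below 45 mg/dL), with
hypoglycemia taking precedence when both bounds are violated. Reward
windows span 4 h and are truncated at the next bolus event.

**Training** seeds per-network replay memories by random acting over the
three-meal training protocol (breakfast 08:00 30-50 g, lunch 14:00
50-70 g, dinner 20:00 60-80 g), then iterates: one closed-loop day per
iteration under a linearly annealed epsilon-greedy policy (1.0 to 0.05),
replay updates (batch 32, Adam, learning rate 1e-3, discount 0.9) of the
networks that acted against a target network synchronized every 15
iterations, and a per-day hypoglycemia-event log (an event is >= 15
consecutive minutes below 70 mg/dL). Training in unannounced mode — boluses
triggered by the detector, as deployed — exposes the agent to the 30-40 min
detection delay; announced-mode training matches the hybrid arm. The loss
is the squared Bellman error
$(r + \gamma \max_{a'} \hat Q(s', a') - Q(s, a))^2$ on uniform mini-batches.

Because the policy is factored across 24 small networks, the Bellman
continuation needs care: the decision after a lunch bolus is taken at the
*next meal's pre-prandial state by the next meal's network*, so the max
term bootstraps from the next event's network (its frozen target copy)
evaluated at that decision state — every network is then only ever
evaluated on states from its own distribution. The last bolus event of a
day is terminal: its value does not bootstrap across the night, where no
action ever intervenes. Three further numerical safeguards matter at desk
scale: rewards are scaled by 1/80 inside the regression (a monotone
rescaling of Q; greedy decisions unchanged, targets O(1)); the output
layer is initialised near zero with a pessimistic bias at the worst scaled
reward, so actions without replay evidence are never preferred over
learned ones; and training ends with offline consolidation epochs on every
network holding at least one batch of data, because networks only receive
online updates when they act and rarely-acting bands would otherwise stay
underfitted. Training episodes run one protocol day plus four hours so the
dinner postprandial window always closes inside the episode; without this
the nocturnal consequences of the dinner bolus would be invisible to the
reward.

**Deployment failsafe.** A network whose replay memory never reached one
batch is flagged untrained; at deployment its band defers to the nearest
trained band of the same meal (or delivers no bolus if the whole meal bank
is untrained) rather than acting on an arbitrary initialisation. Training
and exploration are unaffected.

**Problem sizes.** The package's own experiments and tests train at desk
scale — around 100 memory days and 300-600 iterations per patient, a few
minutes on one CPU — where the learning signal (falling daily hypoglycemia
counts, trained-greedy reward above random) is already unambiguous; the
full-scale configuration (1500 days, 1500 iterations) is the default of
`train_config()` and runs unchanged, only longer.

## Delivery arms and evaluation

`run_arm()` wires three systems over the 14-day four-meal testing protocol
(breakfast 07:00 30-50 g, lunch 13:00 50-70 g, snack 17:00 30-50 g, dinner
20:00 60-80 g, all times jittered +/- 30 min):

- **HAID SBC MCHO** — meals announced; bolus = CHO/CR + (BG-120)/CF - IOB
  with CHO misestimated by a Gaussian of CV 20%;
- **HAID DRL** — meals announced; the DRL bolus at meal time;
- **FAID** — meals unannounced; the DRL bolus at detector flags only. True
  meal times are visible only to the scorer, never to any controller
  component.

The per-tick order is: sense CGM, detector (FAID only), bolus decision,
PD + IFB + pump cap, IOB/SAFE update, deliver, advance the patient 5 min
(RK4 at 1-min substeps). Outcomes are the consensus CGM metrics — band
percentages over {<54, 54-69, 70-140, 70-180, 181-250, >250} mg/dL,
CV, GMI = 3.31 + 0.02392 x mean, and
GRI = 3.0(<54) + 2.4(54-69) + 1.6(>250) + 0.8(181-250) capped at 100 —
plus insulin totals, compared patient-by-patient with two-sided Wilcoxon
signed-rank tests. The GMI and GRI coefficient sets are the standard
published ones. Snacks detected by the FAID arm are routed to the nearest
meal bank (the dinner bank for the 17:00 window); the agents themselves
cover the three main meals, as in the underlying method.

## Numerical and design notes

- Fixed-step RK4 throughout (1-min plant substep; one step per 5-min
  sample inside the UKF); the linear IOB/BOB models use exact closed-form
  steps. Halving the plant substep changes a 24-h trajectory by < 0.1%.
- Ties in greedy action selection break toward the lower index — the
  smaller bolus — as a safety default.
- The sliding-surface bound is constant, so its derivative term is zero;
  a time-varying bound would re-enter through the same expression.
- Plasma glucose is floored at 20 mg/dL with a warning (states below that
  are outside the model's validity); CGM readings clamp at zero.
- All randomness (sensor noise, meal draws, misestimation, exploration,
  weight initialisation) flows through explicit integer seeds; identical
  seeds reproduce traces bit-for-bit.
- Policies serialize to a single JSON file (weights, grids, update counts,
  manifest); configs to YAML with schema-checked top-level blocks.

## Known limitations

- Detector and plant share model structure, so detection sensitivity is
  optimistic; against a structurally different simulator the calibrated
  thresholds would need re-tuning.
- The single-potency minimal model cannot honour the 500/1800 guideline
  rules exactly at all operating points (discussed above).
- Training at desk scale leaves rare (meal, band) networks untrained;
  the deployment failsafe covers them, at the cost of band-specific
  nuance in those regions.
- Nocturnal meals are invisible by design (night suppression); the FAID
  arm relies on the PD loop overnight.
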