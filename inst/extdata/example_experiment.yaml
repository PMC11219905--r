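# Example experiment configuration: 14-day in-silico trial with the
# four-meal testing protocol (breakfast 07:00, lunch 13:00, snack 17:00,
# dinner 20:00; +/- 30 min jitter) for one virtual patient.
patient:
  p1: 0.01            # 1/min, insulin-independent glucose utilisation
  p2: 0.02            # 1/min, remote-insulin disappearance
  p3: 2.5e-5          # 1/min^2 per mU/L, insulin sensitivity
  Gbl: 170            # mg/dL, zero-insulin glucose asymptote
  body_weight: 70     # kg
  kf: 0.138           # 1/min, plasma-insulin clearance
  tmaxI: 55           # min, s.c. insulin time-to-peak
  kdia: 0.025         # 1/min, duration-of-insulin-action constant
  tau_s: 10           # min, sensor lag
  g_s: 1.0            # sensor gain
  TDI: 30             # U/day, total insulin requirement
  ubl: 0.232          # U/h, basal rate
  tmax_meal: 40       # min, meal absorption time-to-peak
  bioavailability: 0.8
variability:
  si_amplitude: 0.2   # circadian insulin-sensitivity amplitude
  si_phase: 600       # min, sensitivity minimum near 04:00
  absorption_cv: 0.2  # per-meal absorption-rate CV
  cgm_noise_sd: 2     # mg/dL
controller:
  tau_d: 90           # min
  Gref: 120           # mg/dL
  nu_plus: 100        # mg/dL, SAFE switching amplitude
  lam: 0.05           # 1/min, SAFE filter rate
  tau_sm: 20          # min, sliding-surface constant
  eta: 0.3            # U/h per mU/L, insulin feedback gain
  pump_max: 6         # U/h
detector:
  mode: trade_off     # trade_off | highest_sensitivity | lowest_fp
  night_start: 23
  night_end: 6
  refractory_min: 120
therapy:
  rule_cr: 500        # CR = rule_cr / TDI (g/U)
  rule_cf: 1800       # CF = rule_cf / TDI (mg/dL per U)
  target: 120         # mg/dL
  mis_sigma: 0.2      # CHO misestimation CV
training:
  gamma: 0.9
  alpha: 0.001
  batch_size: 32
  target_sync_period: 15
  memory_days: 1500
  iterations: 1500
  epsilon_start: 1.0
  epsilon_end: 0.05
experiment:
  arm: faid           # faid | haid_sbc | haid_drl | pd_only
  n_patients: 1
  days: 14
  meals_per_day: 4
  meal_time_jitter_min: 30
  seed: 7
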