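# Default in-silico experiment: 20 synthetic participants, two-phase true
# dynamics with 20% parameter variability, HRV-like disturbance of 2 bpm and
# 1 bpm measurement noise, study protocol timing.
cohort:
  n: 20
  seed: 1
  cv: 0.2
disturbance:
  sd_bpm: 2.0
  cutoff_hz: 0.05
noise_sd_bpm: 1.0
protocol:
  measurement_s: 2100
  eval_start_s: 295
  eval_end_s: 2095
  control_Ts: 5
  hr_sample_hz: 1
saturation:
  u_min: 0.5
  u_max: 6.0
rise_time_s: 150
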