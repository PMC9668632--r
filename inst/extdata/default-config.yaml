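# Default analysis configuration.
# Analysis constants follow the reference methodology; cohort settings
# control the synthetic generator.
seed: 1
cohort:
  n_hc: 101          # healthy controls
  n_mild: 39         # patients with mild-moderate disability (EDSS >= 2)
  n_nodis: 36        # patients without disability (EDSS <= 1)
  n_components: 47   # signal components
  n_timepoints: 255  # TRs per scan
  TR: 2.25           # seconds
  missingness_rate: 0.08
prep:
  enabled: false     # synthetic component signals need no nuisance removal
  despike_c: 4       # MAD multiplier for winsorization
  band: [0.01, 0.15] # Hz; Nyquist at TR 2.25 s is ~0.222 Hz
window:
  w: 22              # window length in TR
  s: 1               # slide length in TR
  taper: none        # or "gaussian" (sigma 3 TR)
clustering:
  k: null            # null: select via elbow + Dunn's index convergence
  k_range: [2, 10]
  n_init: 20
  max_points: 2000
stats:
  n_perm: 999
  alpha: 0.05
  lower_pct: 30      # EDSS percentile cuts
  upper_pct: 70
  gate_posthoc: false
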