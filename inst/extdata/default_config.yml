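# Default analysis configuration: reproduces the measurement-campaign setup.
# Any subset of keys may appear; missing keys fall back to these values.

# physics
calibration_factor: 2.3        # instrument reading -> Rn-219 concentration
evaluability_limit_kbq_m3: 600 # readings below this cannot be evaluated
range_limit_kbq_m3: 2000       # display saturates above this reading
tube_volume_ml: 20             # sampling-tube volume
half_life_s: 3.98              # Rn-219 half-life
background_kbq_l: 0            # optional per-session background offset

# campaign filtering
non_evaluable_models: ["P30F"]

# censored-lognormal statistics
plotting_convention: hazen     # hazen (i-0.5)/n, weibull i/(n+1), blom
percentile_method: distributional
include_less_than_in_fit: true

# recording combination
use_printed_final: true        # trust a fixture's printed final results
use_printed_decay_factor: true # trust a fixture's printed decay factors
outlier_heuristic: false       # auto-discard less-than paired with a point

# blood-clearance factors (external pharmacokinetics literature)
clearance_factors:
  early_to_late: 3
  one_min_to_4h: 22.5
  early_to_late_band: [4.1, 5.5]
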