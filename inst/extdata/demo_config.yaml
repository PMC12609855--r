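# Demo configuration for lipidval::run_validation().
# Synthetic validation-wave cohort (n = 1099), outcomes simulated from
# the non-HDL-C equation with the observed-regime miscalibration
# (intercept drift -0.07, slope drift 0.71), then the full pipeline.
seed: 1
out_dir: lipidval_demo_output
cohort:
  spec:
    n: 1099
model: nonhdl
simulate:
  drift_intercept: -0.07
  drift_slope: 0.71
recalibrate:
  method: joint
dca:
  grid_min: 0.01
  grid_max: 0.60
  grid_step: 0.01
samplesize: nonhdl
benchmark:
  B: 200
fairness: true
figures: false
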