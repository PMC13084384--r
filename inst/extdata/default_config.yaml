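## Default run configuration: the thin (0.3 mm) reference case simulated
## over 23 years on a monthly output grid, with the clinically defined
## high-risk Agatston threshold of 400.
case:
  name: thin
run:
  horizon_years: 23
  output_months: 1
  threshold: 400
  side: ventricular
solver:
  rtol: 1.0e-6
  atol_scale: 1.0e-6
  method: lsoda
  check_tolerance: false
paths:
  parameters: ~
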