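# Diffusion-dominated (Stefan) peeling run at constant contact angle.
# Usage: Rscript inst/cli/mempeel.R run --config inst/examples/stefan.yaml --out stefan_run
modes:
  regime: diffusion
  constant_theta: true
run:
  t_end: 1.25           # seconds; 0.05 * tau_diff1
  theta_fixed_deg: 20.53  # driving parameter U = 2
  snap_times: 1.25
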