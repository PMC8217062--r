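# Set A validation conditions: 5.89 mL test tube in a 37 °C water bath,
# irrigation at 23 °C, fitted wall-loss coefficient 1.15 W/°C
# (values near 1.14 have also been reported for this vessel).
volume_ml: 5.89
t0_c: 37
t_in_c: 23
beta_w_per_c: 1.15
flow_ml_min: 0
laser:
  - on_s: 20
    off_s: 80
    power_w: 40
fluid:
  k: 0.606
  rho: 1000.0
  c: 4180.0
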