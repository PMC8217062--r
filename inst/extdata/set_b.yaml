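# Set B validation conditions: 38.3 mL cylindrical vessel, room-temperature
# bath and irrigation (22 °C), fitted wall-loss coefficient 1.36 W/°C.
volume_ml: 38.3
t0_c: 22
t_in_c: 22
beta_w_per_c: 1.36
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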