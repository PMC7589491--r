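# Demo configuration for the franzpampa pipeline.
# sample_volume is an operational autosampler setting, not a cell constant;
# 1.0 mL is an assumption documented with the package, not a measured value.
geometry:
  area: 1.77            # membrane diffusion area, cm2
  donor_volume: 1.0     # mL
  receiver_volume: 7.0  # mL
  sample_volume: 1.0    # mL withdrawn and replaced per sampling event
schedule:
  times: [0.25, 0.5, 1.0, 2.0, 3.0, 4.0, 5.0, 6.0, 10.0, 12.0]  # hours
simulation:
  true_peff: 1.0e-5            # cm/s
  donor_concentration_0: 10000 # ug/mL (10 mg/mL donor load)
  n_replicates: 3
  noise_cv: 0.05
  seed: 1
fitting:
  method: both          # sink | nonsink | both
  qtotal_mode: mass_conserving
  min_window: 4
correlation:
  papp_column: papp_franz
  form: log-linear
  exclude: [ranitidine, trimethoprim, verapamil]
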