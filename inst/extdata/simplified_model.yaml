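# Calibrated parameter adaptations of the Simplified Model (see the
# methods vignette and calibrate_simplified()).  Rates in Hz, drives in
# kHz, currents in pA; weight scalings are dimensionless multipliers of
# the corresponding Complete-Model synaptic weights.
targets:
  D2: 1.5
  FSN: 15.0
  GPTI: 50.0
  STN: 16.0
nu_ext:
  D2: 1.0141
  FSN: 0.9125
  GPTIA: 0.7440
  GPTIB: 1.4073
  STN: 0.5514
I_e: {}
aux_nu_ext:
  D2s: 0.6684
  STNs: 0.1211
  GPTIs: 0.5229
loop_weight_scale:
  A: 1.4
  B: 1.75
gpti_cross: epsilon
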