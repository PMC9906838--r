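# Illustrative synthetic transcription of a PREDICT-style ER-positive model.
# These are NOT the published v2.1 constants (which are not redistributed
# here); replace coefficients and baseline with a faithful transcription for
# real-data runs. The structure (term transforms, treatment log-HRs,
# tabulated baseline with cloglog interpolation) is what the engine tests.
er_stratum: positive
terms:
  - variable: age
    type: numeric
    transform: identity
    reference: 60
    coefficient: 0.016
  - variable: size_mm
    type: numeric
    transform: log
    reference: 20
    coefficient: 0.45
  - variable: nodes
    type: numeric
    transform: log1p
    reference: 0
    coefficient: 0.55
  - variable: grade
    type: numeric
    transform: identity
    reference: 1
    coefficient: 0.40
  - variable: her2
    type: numeric
    transform: identity
    reference: 0
    coefficient: 0.25
  - variable: ki67
    type: numeric
    transform: identity
    reference: 0
    coefficient: 0.12
  - variable: detection
    type: categorical
    reference: symptomatic
    level_coefficients:
      screen: -0.25
      unknown: 0.0
treatment_log_hr:
  hormone: -0.3857
  chemo_second: -0.2485
  chemo_third: -0.36
  trastuzumab: -0.357
baseline:
  time: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
  survival: [1.0, 0.995, 0.989, 0.982, 0.975, 0.968, 0.961, 0.954, 0.947,
             0.940, 0.933, 0.927, 0.921, 0.915, 0.909, 0.903]
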