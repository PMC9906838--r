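# Illustrative synthetic ER-negative companion spec (see er_positive.yaml).
# ER-negative disease has its own, steeper early baseline hazard; KI67 does
# not enter this stratum.
er_stratum: negative
terms:
  - variable: age
    type: numeric
    transform: identity
    reference: 60
    coefficient: 0.010
  - variable: size_mm
    type: numeric
    transform: log
    reference: 20
    coefficient: 0.40
  - variable: nodes
    type: numeric
    transform: log1p
    reference: 0
    coefficient: 0.50
  - variable: grade
    type: numeric
    transform: identity
    reference: 1
    coefficient: 0.30
  - variable: her2
    type: numeric
    transform: identity
    reference: 0
    coefficient: 0.20
  - variable: detection
    type: categorical
    reference: symptomatic
    level_coefficients:
      screen: -0.20
      unknown: 0.0
treatment_log_hr:
  hormone: 0.0
  chemo_second: -0.30
  chemo_third: -0.42
  trastuzumab: -0.357
baseline:
  time: [0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
  survival: [1.0, 0.975, 0.945, 0.915, 0.890, 0.870, 0.855, 0.843, 0.833,
             0.825, 0.818, 0.812, 0.807, 0.803, 0.799, 0.796]
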