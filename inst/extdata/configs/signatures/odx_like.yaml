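# Illustrative recurrence-score-style linear signature for z-scored data.
# Weights are editable defaults, not the proprietary assay constants:
# proliferation and HER2 genes push risk up, oestrogen-axis genes pull it
# down. Scores are shifted and clipped to a 0-20 display scale.
name: odx_like
archetype: linear
offset: 10
scale_bounds: [0, 20]
gene_weights:
  AURKA: 1.04
  BIRC5: 1.04
  CCNB1: 1.04
  MKI67: 1.04
  MYBL2: 1.04
  ERBB2: 0.94
  GRB7: 0.94
  ESR1: -0.84
  PGR: -0.84
  BCL2: -0.84
  SCUBE2: -0.84
  MMP11: 0.54
  CTSV: 0.54
  GSTM1: -0.28
  BAG1: -0.28
  CD68: 0.14
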