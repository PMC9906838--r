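# Illustrative template-correlation signature: Pearson correlation of each
# patient's profile with a good-prognosis reference profile; higher
# correlation = better prognosis (so its Cox coefficient is expected to be
# negative). risk_cutoff attaches the conventional two-level risk group.
name: mammaprint_like
archetype: template
correlation: pearson
risk_cutoff: 0.4
template:
  BBC3: 0.5
  EGLN1: 0.4
  ESM1: -0.6
  IGFBP5: 0.7
  FGF18: -0.3
  SCUBE2: 0.8
  TGFB3: 0.6
  WISP1: 0.4
  FLT1: -0.5
  HRASLS: 0.3
  STK32B: -0.4
  RASSF7: -0.3
  DCK: -0.5
  MELK: -0.8
  GNAZ: -0.2
  EXT1: 0.3
  GMPS: -0.6
  GPR180: -0.4
  MCM6: -0.7
  NMU: -0.5
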