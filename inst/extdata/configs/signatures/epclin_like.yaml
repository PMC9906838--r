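# Clinically combined EndoPredict-style variant: the same molecular score
# plus tumour-size and nodal terms, expressed as clinical_terms so the
# combination is configuration, not a separate code path.
name: epclin_like
archetype: linear
offset: 2
gene_weights:
  BIRC5: 0.91
  UBE2C: 0.70
  DHCR7: 0.53
  RBBP8: -0.61
  IL6ST: -0.84
  AZGP1: -0.52
  MGP: -0.37
  STC2: -0.59
clinical_terms:
  size_mm: 0.02
  nodes: 0.30
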