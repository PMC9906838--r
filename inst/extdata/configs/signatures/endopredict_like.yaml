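# Illustrative EndoPredict-style weighted sum over eight informative genes
# (z-scored input); molecular score only — see epclin_like.yaml for the
# clinically combined variant.
name: endopredict_like
archetype: linear
offset: 5
scale_bounds: [0, 15]
gene_weights:
  BIRC5: 0.91
  UBE2C: 0.70
  DHCR7: 0.53
  RBBP8: -0.61
  IL6ST: -0.84
  AZGP1: -0.52
  MGP: -0.37
  STC2: -0.59
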