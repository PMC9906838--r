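# Illustrative risk-of-recurrence-style centroid signature: Spearman
# correlation of each patient's profile with four intrinsic-subtype
# centroids, combined by class weights (aggressive subtypes weighted up).
# See rorc_like.yaml for the clinical "-C" variant.
name: prosigna_like
archetype: centroid
correlation: spearman
offset: 0
class_weights:
  lumA: -0.62
  lumB: 0.35
  her2e: 0.61
  basal: 0.79
centroids:
  gene:  [ESR1, PGR, FOXA1, BCL2, ERBB2, GRB7, MKI67, AURKA, CCNE1, KRT5]
  lumA:  [ 0.9,  0.8,  0.85,  0.7, -0.3, -0.3, -0.6,  -0.6,  -0.5, -0.6]
  lumB:  [ 0.6,  0.3,  0.55,  0.2, -0.1, -0.1,  0.5,   0.6,   0.4, -0.5]
  her2e: [-0.4, -0.5, -0.20, -0.3,  0.9,  0.9,  0.4,   0.4,   0.3, -0.2]
  basal: [-0.8, -0.7, -0.75, -0.5, -0.3, -0.3,  0.6,   0.6,   0.7,  0.9]
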