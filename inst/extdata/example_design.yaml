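# Example simulation design: the default 54-death validation-series
# conditions, written out explicitly. Any entry may be omitted to keep the
# package default. Probability vectors must sum to 1 (tolerance 1e-9), hence
# the full-precision decimals.
n_cases: 54
seed: 7
category_probs:
  infectious_diseases: 0.7777777777777778
  malignant_tumors: 0.12962962962962962
  congenital_malformations: 0.037037037037037035
  other_diseases: 0.05555555555555555
  nonconclusive: 0.0
confusion:
  - [0.9285714285714286, 0.0, 0.0, 0.023809523809523808, 0.047619047619047616]
  - [0.0, 1.0, 0.0, 0.0, 0.0]
  - [1.0, 0.0, 0.0, 0.0, 0.0]
  - [0.3333333333333333, 0.0, 0.0, 0.6666666666666666, 0.0]
  - [0.0, 0.0, 0.0, 0.0, 1.0]
depth_agreement:
  perfect: 0.5
  almost_perfect: 0.16666666666666666
  moderate: 0.08333333333333333
  low: 0.0625
mia_certainty:
  low: 0.07692307692307693
  moderate: 0.21153846153846154
  high: 0.3269230769230769
  very_high: 0.38461538461538464
cda_certainty:
  low: 0.05555555555555555
  moderate: 0.12962962962962962
  high: 0.37037037037037035
  very_high: 0.4444444444444444
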