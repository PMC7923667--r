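country: Thailand
diet_kcal: 2000
discretionary_kcal: 0
notes: >
  Grains group includes roots and tubers; fruit originally recommended in
  pieces (one piece taken as one cup); no oils/fats recommendation.
recommendations:
- group: protein_foods
  amount: 135
  unit: g
- group: dairy
  amount: 237
  unit: ml
- group: grains
  amount: 600
  unit: g
- group: fruit
  amount: 784
  unit: g
- group: vegetables
  amount: 200
  unit: g
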