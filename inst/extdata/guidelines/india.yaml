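country: India
diet_kcal: 2000
discretionary_kcal: 0
notes: >
  Protein-foods group covers pulses only (plant proteins); sugar quantified at
  30 g/d.
recommendations:
- group: protein_foods
  amount: 75
  unit: g
  allowed_commodities:
  - Beans
  - Peas
  - Pulses, other and products
- group: dairy
  amount: 300
  unit: ml
- group: grains
  amount: 330
  unit: g
- group: fruit
  amount: 100
  unit: g
- group: vegetables
  amount: 500
  unit: g
- group: oils_fats
  amount: 25
  unit: g
- group: sugar
  amount: 30
  unit: g
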