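country: US Vegetarian
diet_kcal: 2000
discretionary_kcal: 290
notes: >
  Vegetarian adaptation: protein foods restricted to plant proteins and eggs;
  290 discretionary kcal without a composition.
recommendations:
- group: protein_foods
  amount: 97
  unit: g
  allowed_commodities:
  - Beans
  - Peas
  - Pulses, other and products
  - Soyabeans
  - Nuts and products
  - Eggs
- group: dairy
  amount: 710
  unit: ml
- group: grains
  amount: 184
  unit: g
- group: fruit
  amount: 392
  unit: g
- group: vegetables
  amount: 350
  unit: g
- group: oils_fats
  amount: 27
  unit: g
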