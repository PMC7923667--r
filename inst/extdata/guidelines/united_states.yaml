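country: United States
diet_kcal: 2000
discretionary_kcal: 270
notes: >
  2000-kcal pattern; 270 discretionary kcal included without a composition;
  fruit recommendation of 2 cups/d expressed here as its gram equivalent.
recommendations:
- group: protein_foods
  amount: 156
  unit: g
- group: dairy
  amount: 710
  unit: ml
- group: grains
  amount: 170
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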