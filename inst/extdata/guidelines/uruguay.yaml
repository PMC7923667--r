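country: Uruguay
diet_kcal: 2000
discretionary_kcal: 0
notes: >
  Scaled from the 2200-kcal pattern; protein foods cover eggs, fish and
  seafood, and meat; fruit and vegetables form one combined group; sugar
  quantified at 60 g/d (scaled).
recommendations:
- group: protein_foods
  amount: 91
  unit: g
  allowed_commodities:
  - Eggs
  - Freshwater fish
  - Marine fish, other
  - Bovine meat
  - Mutton and goat meat
  - Pig meat
  - Poultry meat
- group: dairy
  amount: 455
  unit: ml
- group: grains
  amount: 227
  unit: g
- group: fruit_and_vegetables
  amount: 455
  unit: g
- group: oils_fats
  amount: 25
  unit: g
- group: sugar
  amount: 60
  unit: g
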