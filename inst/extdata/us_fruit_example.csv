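commodity,proportion,cup_to_kg,kg_co2e_per_kg,ghge_printed
Apples and products,0.178,0.110,0.228,0.009
Bananas,0.113,0.150,0.374,0.013
"Citrus, other",0.002,0.185,0.438,0.000
Dates,0.001,0.075,2.024,0.000
Grapefruits and products,0.017,0.210,1.210,0.008
Grapes and products,0.085,0.120,0.478,0.010
"Lemons, limes, and products",0.091,0.210,0.517,0.020
"Oranges, tangerines, mandarins, and products",0.231,0.185,0.347,0.030
Pineapples and products,0.061,0.165,0.914,0.018
"Fruits, other",0.222,0.196,0.652,0.057
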