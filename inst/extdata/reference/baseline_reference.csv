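country,protein_foods,dairy,grains,fruit,vegetables,oils_fats,fruit_and_vegetables,total,has_sugar,has_discretionary
Germany,0.98,0.81,0.05,0.12,0.20,0.09,NA,2.25,TRUE,FALSE
India,0.03,0.41,0.11,0.05,0.17,0.08,NA,0.86,TRUE,FALSE
Oman,1.24,0.17,0.20,0.39,0.27,0.26,NA,2.53,FALSE,FALSE
Netherlands,1.12,0.89,0.08,0.08,0.12,0.15,NA,2.86,FALSE,TRUE
Thailand,0.63,0.33,0.31,0.47,0.09,NA,NA,1.83,FALSE,FALSE
United States,1.84,1.10,0.02,0.16,0.16,0.03,NA,3.83,FALSE,TRUE
US Vegetarian,0.06,1.10,0.02,0.16,0.16,0.03,NA,1.80,FALSE,TRUE
Uruguay,1.50,0.65,0.03,NA,NA,0.04,0.18,2.42,TRUE,FALSE
EAT-Lancet,0.79,0.30,0.03,0.08,0.12,0.05,NA,1.36,FALSE,FALSE
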