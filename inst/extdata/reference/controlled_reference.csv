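country,protein_foods,dairy,grains,fruit,vegetables,oils_fats,fruit_and_vegetables,total,ratio_to_reference,has_sugar,has_discretionary
Germany,1.37,0.81,0.05,0.12,0.18,0.05,NA,2.61,1.47,TRUE,FALSE
India,0.02,0.41,0.05,0.05,0.18,0.03,NA,0.74,5.19,TRUE,FALSE
Oman,1.14,0.18,0.44,0.29,0.18,0.05,NA,2.29,1.68,FALSE,FALSE
Netherlands,1.51,0.90,0.08,0.09,0.11,0.04,NA,3.22,1.19,FALSE,TRUE
Thailand,1.61,0.37,0.09,0.47,0.09,NA,NA,2.63,1.46,FALSE,FALSE
United States,1.84,1.10,0.02,0.16,0.16,0.03,NA,3.83,1.00,FALSE,TRUE
US Vegetarian,0.06,1.10,0.02,0.16,0.16,0.03,NA,1.80,2.13,FALSE,TRUE
Uruguay,1.24,0.70,0.03,NA,NA,0.02,0.19,2.22,1.73,TRUE,FALSE
EAT-Lancet,0.79,0.30,0.03,0.08,0.12,0.05,NA,1.36,2.82,FALSE,FALSE
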