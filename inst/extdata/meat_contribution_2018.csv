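category,nutrient_id,all_meat,ruminant_meat,poultry_meat,pig_meat,other_meat,offal_and_fats
macronutrient,carbohydrates,<0.5,<0.5,<0.5,<0.5,<0.5,<0.5
macronutrient,energy,11,2,2,4,<0.5,2
macronutrient,fat,29,5,6,12,<0.5,5
macronutrient,fiber,No contribution,No contribution,No contribution,No contribution,No contribution,No contribution
macronutrient,protein,21,6,6,7,1,1
mineral,calcium,4,<0.5,3,1,<0.5,<0.5
mineral,copper,10,1,1,1,<0.5,7
mineral,iron,13,3,3,2,1,4
mineral,magnesium,3,1,1,1,<0.5,<0.5
mineral,phosphorus,11,3,3,4,<0.5,1
mineral,potassium,7,2,1,2,<0.5,1
mineral,selenium,18,3,4,9,<0.5,2
mineral,zinc,19,8,4,5,1,2
vitamin,vitamin_a,24,<0.5,7,<0.5,<0.5,17
vitamin,vitamin_b1,15,1,1,8,<0.5,1
vitamin,vitamin_b2,15,3,3,4,<0.5,5
vitamin,vitamin_b5,10,1,4,2,<0.5,3
vitamin,vitamin_b6,13,3,4,4,1,1
vitamin,vitamin_b9,4,<0.5,2,<0.5,<0.5,1
vitamin,vitamin_b12,56,14,5,5,1,31
vitamin,vitamin_c,1,No contribution,1,<0.5,<0.5,<0.5
vitamin,vitamin_e,1,<0.5,<0.5,1,<0.5,<0.5
amino_acid,cystine,16,5,5,5,<0.5,1
amino_acid,histidine,26,7,7,9,1,1
amino_acid,leucine,21,7,6,7,1,1
amino_acid,lysine,32,10,10,10,1,2
amino_acid,methionine,25,8,8,7,1,1
amino_acid,threonine,25,8,7,8,1,1
amino_acid,tryptophan,19,6,5,6,<0.5,1
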