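component,column,scale,per_1000kcal,max_points,best,zero
total_fruit,fruit_day,0.5,1,5,0.8,0
whole_fruit,whole_fruit_day,1,1,5,0.4,0
total_vegetables,vegetables_day,0.0625,1,5,1.1,0
greens_and_beans,greens_beans_day,1,1,5,0.2,0
whole_grains,whole_grains_day,1,1,10,1.5,0
dairy,dairy_day,1,1,10,1.3,0
total_protein,protein_day,1,1,5,2.5,0
seafood_plant_protein,seafood_plant_day,1,1,5,0.8,0
fatty_acids,fa_ratio,1,0,10,2.5,1.2
refined_grains,refined_grains_day,1,1,10,1.8,4.3
sodium,sodium_mg_day,0.001,1,10,1.1,2.0
added_sugars,added_sugar_pct_energy,1,0,10,6.5,26
saturated_fat,sat_fat_pct_energy,1,0,10,8,16
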