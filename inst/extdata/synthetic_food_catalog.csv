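item_id,grams_per_serving,mufa_per_100g,sfa_per_100g,group
veg_salad,100,0.1,0.05,vegetables
veg_cooked,150,0.1,0.05,vegetables
veg_soup,250,0.8,0.3,vegetables
leg_beans,130,0.2,0.1,legumes
leg_chickpeas,130,1.0,0.3,legumes
fruit_apple,140,0.01,0.03,fruits
fruit_orange,150,0.02,0.02,fruits
fruit_melon,200,0.01,0.02,fruits
cer_bread,50,0.4,0.3,cereals
cer_rice,150,0.2,0.2,cereals
cer_pasta,150,0.2,0.1,cereals
fish_white,120,0.5,0.3,fish
fish_oily,100,4.5,2.5,fish
meat_beef,120,4.5,4.0,meat
meat_pork,120,4.0,3.5,meat
meat_processed,50,6.0,6.0,meat
dairy_milk,240,1.0,2.3,dairy
dairy_cheese,40,7.5,17.0,dairy
dairy_yogurt,125,0.8,1.7,dairy
alc_wine,12,0,0,alcohol
alc_beer,10,0,0,alcohol
fat_oliveoil,10,73.0,14.0,fat_only
fat_butter,10,21.0,51.0,fat_only
fat_margarine,10,30.0,16.0,fat_only
oth_sweets,50,8.0,10.0,other
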