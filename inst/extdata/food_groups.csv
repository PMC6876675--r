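category,hdds,cdds,fgds,vita,fcs
cereals,starchy_staples,starchy_staples,starchy_staples,,staples
roots_tubers,starchy_staples,starchy_staples,starchy_staples,,staples
vita_vegetables,vegetables,vita_fruit_veg,vita_vegetables,vita_vegetables,vegetables
other_vegetables,vegetables,other_fruit_veg,other_fruit_veg,,vegetables
vita_fruits,fruits,vita_fruit_veg,vita_fruits,vita_fruits,fruit
other_fruits,fruits,other_fruit_veg,other_fruit_veg,,fruit
organ_meat,meat,organ_meat,organ_meats,organ_meat,meat_fish
flesh_meat_fish,meat,flesh_foods,flesh_foods,flesh_meat,meat_fish
eggs,eggs,eggs,eggs,eggs,meat_fish
legumes_nuts,legumes_nuts,legumes_nuts,legumes_nuts,,pulses
milk_dairy,dairy,dairy,dairy,dairy,milk
oils_fats,oil,,oil,,oil_sugar
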