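food_id,name,calories,carbs_g,protein_g,fat_g,fiber_g,glycemic_index,tags
F001,white rice cooked,340,74,6.6,0.6,1.0,73,vegetarian
F002,brown rice cooked,330,68,6.9,2.4,3.4,68,vegetarian
F003,quinoa cooked,300,53,11.0,4.8,7.0,53,vegetarian
F004,white bread two slices,180,32,6.0,2.2,1.6,75,vegetarian;contains_gluten
F005,whole wheat bread two slices,180,30,8.0,2.6,5.2,59,vegetarian;contains_gluten
F006,chapati two pieces,240,44,7.6,5.4,6.2,62,vegetarian;contains_gluten
F007,idli three pieces,210,44,7.2,0.9,2.4,77,vegetarian
F008,dosa plain,250,42,6.5,7.0,2.6,66,vegetarian
F009,potato boiled,190,43,4.0,0.2,3.8,78,vegetarian
F010,sweet potato baked,200,46,3.6,0.3,6.6,63,vegetarian
F011,pasta cooked,310,60,11.0,1.8,3.6,49,vegetarian;contains_gluten
F012,oat porridge,230,40,8.4,4.6,6.0,55,vegetarian;contains_gluten
F013,cornflakes with milk,250,48,7.8,3.2,1.4,81,vegetarian
F014,muesli with milk,290,46,10.5,7.2,5.4,57,vegetarian;contains_nut
F015,banana large,120,31,1.5,0.4,3.5,51,vegetarian
F016,apple medium,95,25,0.5,0.3,4.4,36,vegetarian
F017,orange medium,70,18,1.3,0.2,3.1,43,vegetarian
F018,mango cup,100,25,1.4,0.6,2.6,56,vegetarian
F019,grapes cup,104,27,1.1,0.2,1.4,59,vegetarian
F020,watermelon two cups,92,23,1.8,0.4,1.2,76,vegetarian
F021,dal lentil curry,230,34,13.0,4.5,9.0,29,vegetarian
F022,chickpea curry,270,38,12.5,7.5,10.5,28,vegetarian
F023,kidney bean curry,250,37,13.5,4.8,11.0,24,vegetarian
F024,sweetened yogurt cup,190,30,8.5,3.3,0.0,41,vegetarian
F025,plain yogurt cup,110,9,9.5,4.8,0.0,19,vegetarian
F026,milk glass,150,12,8.0,8.0,0.0,39,vegetarian
F027,grilled chicken breast,220,0,41.0,5.0,0.0,0,
F028,grilled fish fillet,190,0,36.0,4.5,0.0,0,
F029,boiled eggs two,140,1,12.6,9.5,0.0,0,vegetarian
F030,paneer cubes,265,4,18.0,20.5,0.0,27,vegetarian
F031,tofu stir fry,180,9,17.5,10.0,2.8,15,vegetarian
F032,mixed green salad,90,9,3.0,5.0,4.2,15,vegetarian
F033,vegetable soup bowl,120,18,4.5,3.0,4.8,38,vegetarian
F034,mixed nuts handful,170,6,5.5,15.0,2.4,22,vegetarian;contains_nut
F035,peanut butter toast,260,30,10.5,12.5,3.6,55,vegetarian;contains_nut;contains_gluten
F036,granola bar,190,29,4.0,7.0,2.8,61,vegetarian;contains_nut;contains_gluten
F037,fruit juice glass,140,34,0.8,0.2,0.4,66,vegetarian
F038,cola can,140,39,0.0,0.0,0.0,63,vegetarian
F039,chocolate bar,230,26,3.2,13.0,2.2,49,vegetarian
F040,ice cream scoop,210,24,3.6,11.0,0.6,51,vegetarian
F041,samosa two pieces,300,34,6.0,16.0,2.8,72,vegetarian;contains_gluten
F042,pizza two slices,480,58,20.0,18.5,3.6,60,vegetarian;contains_gluten
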