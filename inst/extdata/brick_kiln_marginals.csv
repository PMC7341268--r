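question_id,response,donkey,horse,mule
nut_bcs,Very thin/poor,1.9,9.1,2.1
nut_bcs,Thin/moderate,58.5,50.0,42.3
nut_bcs,Ideal,37.7,38.8,53.4
nut_bcs,Fat,1.9,2.2,2.2
nut_bcs,Very fat,0,0,0
nut_diet,Pasture,25.8,27.4,27.4
nut_diet,Vitamins/minerals,8.3,10.9,10.9
nut_diet,Browse,6.9,3.5,2.6
nut_diet,Straw/stover,0.5,0.6,0.9
nut_diet,Chopped fibre/chaff,0,1.1,0.7
nut_diet,Hay,0,0.4,0.6
nut_diet,Haylage,0,0.1,0.2
nut_diet,Straights,16.1,15.1,14.4
nut_diet,Creep feed,5.5,2.8,2.8
nut_diet,Legumes/pulses,3.2,1.9,1.2
nut_diet,Cereal grains,10.6,9.9,10.8
nut_diet,Mix/muesli,5.5,9.8,10.8
nut_diet,Silage,0,0.2,0.5
nut_water_work,Free access,0,2.7,4.5
nut_water_work,Limited access,95.7,96.5,94.0
nut_water_work,No access,4.3,0.8,1.5
nut_water_housed,Free access,0,2.2,1.6
nut_water_housed,Limited access,96.1,97.3,98.3
nut_water_housed,No access,3.9,0.5,0.1
hlt_lameness,No lameness,90.7,93.8,93.6
hlt_lameness,Lame but still moving,5.6,5.7,6.0
hlt_lameness,Severely lame,3.7,0.5,0.4
hlt_coat,Yes,91.5,88.8,92.4
hlt_coat,No,8.5,11.2,7.6
hlt_skin,No signs present,40.3,41.4,36.1
hlt_skin,Scars,19.4,27.9,33.7
hlt_skin,Alopecia,18.1,16.8,21.2
hlt_skin,Swellings,4.2,1.3,1.2
hlt_skin,Open wounds,18.1,12,7.4
hlt_skin,Sarcoids,0,0.7,0.4
hlt_illness,No signs present,61.1,80.3,88.4
hlt_illness,Eye discharge,11.1,11.4,5.9
hlt_illness,Nasal discharge,19.4,6.9,4.7
hlt_illness,Signs of diarrhoea,8.3,0.5,0.3
hlt_illness,Discharge (penis or vulva),0,0.2,0.3
hlt_illness,Abdominal pain,0,0.7,0.4
beh_harmful,No,61.4,60.0,56.3
beh_harmful,Limb tethering or hobbling,31.6,37.6,42.5
beh_harmful,Amputations or mutilations,3.5,0.1,0.1
beh_harmful,Firing and hot branding,3.5,0.2,0.2
beh_harmful,Rope noseband,0,0,0.1
beh_attitude,At ease,83.6,76.6,70.1
beh_attitude,Alert and active,14.5,21.1,26.5
beh_attitude,"Agitated, aggressive",0,1.1,1.1
beh_attitude,"Apathetic, depressed, withdrawn",1.8,1.3,2.3
beh_fear,No signs of fear and distress present,75.0,77.7,72.9
beh_fear,Head shyness,10.0,5.2,3.8
beh_fear,Unpredictable or sudden movements,8.3,8.2,9.1
beh_fear,Showing the whites of the eyes,0,5.1,9.3
beh_fear,Sudden startle responses,3.3,1.4,1.2
beh_fear,Aggressive behaviour,1.7,2.1,3.2
beh_fear,Trembling,1.7,0.4,0.3
beh_handler,Relaxed and confident,91.4,92.8,90.4
beh_handler,Cautious/fearful,0,6.9,9.0
beh_handler,Assertive/indifferent,8.6,0,0
beh_handler,Aggressive,0,0.4,0.6
wrk_hours,Less than or equal to 3 h,1.8,0.1,0
wrk_hours,"More than 3, less than or equal to 6 h",8.8,5.2,5.5
wrk_hours,"More than 6, less than or equal to 9 h",86.0,94.2,93.5
wrk_hours,More than 9 h,1.8,0.6,0.9
wrk_days,5 days or less,1.8,1.2,0.7
wrk_days,6 days,91.1,84.6,86.4
wrk_days,7 days,7.1,14.2,12.9
wrk_rest,"Yes, equipment removed",1.8,13.3,7.3
wrk_rest,"Yes, equipment not removed",76.4,72.5,84.8
wrk_rest,No,21.8,14.2,7.9
wrk_shade,Access to shade,37.2,23.8,23.4
wrk_shade,Limited access to shade,58.1,72.4,73.6
wrk_shade,No access to shade,4.7,3.7,2.9
hse_regime,Stabled equid - access to field,30.5,26,24.6
hse_regime,Kept outside - access to shelter,0,0.8,0.1
hse_regime,Indoor housing,69.5,73.1,75.0
hse_regime,Kept outside - no access to shelter,0,0,0
hse_clean,Yes,65.5,74.9,85.3
hse_clean,No,34.5,25.1,14.7
hse_dimensions,Satisfactory,61.0,69.8,85.4
hse_dimensions,Not-Satisfactory,39.0,30.2,14.6
hse_lying,Yes,44.1,70.7,82.7
hse_lying,No,55.9,29.3,17.3
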