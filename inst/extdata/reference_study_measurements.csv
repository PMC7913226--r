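study,measurement,category,value
barac_nieto,weight_kg,mild,52.03
barac_nieto,weight_kg,intermediate,48.24
barac_nieto,weight_kg,severe,42.52
barac_nieto,height_cm,mild,156
barac_nieto,height_cm,intermediate,157
barac_nieto,height_cm,severe,156
barac_nieto,bwt_ht_kg_m,mild,33.3
barac_nieto,bwt_ht_kg_m,intermediate,30.8
barac_nieto,bwt_ht_kg_m,severe,27.4
barac_nieto,pct_standard_bwt_ht,mild,89.5
barac_nieto,pct_standard_bwt_ht,intermediate,82.7
barac_nieto,pct_standard_bwt_ht,severe,73.9
barac_nieto,serum_albumin_g_100mL,mild,3.8
barac_nieto,serum_albumin_g_100mL,intermediate,3
barac_nieto,serum_albumin_g_100mL,severe,2.1
barac_nieto,hematocrit,mild,44.4
barac_nieto,hematocrit,intermediate,37.2
barac_nieto,hematocrit,severe,32
barac_nieto,fat_mass_pct,mild,17.7
barac_nieto,fat_mass_pct,intermediate,19.8
barac_nieto,fat_mass_pct,severe,15.2
bosy_westphal,weight_kg,intermediate_weight,70.9
bosy_westphal,weight_kg,underweight,46.3
bosy_westphal,height_cm,intermediate_weight,178
bosy_westphal,height_cm,underweight,165
bosy_westphal,bwt_ht_kg_m,intermediate_weight,39.8
bosy_westphal,bwt_ht_kg_m,underweight,28.1
bosy_westphal,brain_kg,intermediate_weight,1.51
bosy_westphal,brain_kg,underweight,1.13
bosy_westphal,heart_kg,intermediate_weight,0.33
bosy_westphal,heart_kg,underweight,0.22
bosy_westphal,liver_kg,intermediate_weight,1.64
bosy_westphal,liver_kg,underweight,0.94
bosy_westphal,spleen_kg,intermediate_weight,0.23
bosy_westphal,spleen_kg,underweight,0.11
bosy_westphal,kidney_kg,intermediate_weight,0.36
bosy_westphal,kidney_kg,underweight,0.21
bosy_westphal,bone_mineral_content_kg,intermediate_weight,2.68
bosy_westphal,bone_mineral_content_kg,underweight,1.93
bosy_westphal,lean_soft_tissue_trunk_kg,intermediate_weight,24.1
bosy_westphal,lean_soft_tissue_trunk_kg,underweight,16.9
bosy_westphal,skeletal_muscle_mass_kg,intermediate_weight,27.6
bosy_westphal,skeletal_muscle_mass_kg,underweight,16.6
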