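sex,age_months,median_kg,sd_kg
male,3,6.4,0.704
male,6,7.9,0.869
male,12,9.6,1.056
male,24,12.2,1.342
male,36,14.3,1.573
male,48,16.3,1.793
male,60,18.3,2.013
female,3,5.8,0.638
female,6,7.3,0.803
female,12,8.9,0.979
female,24,11.5,1.265
female,36,13.9,1.529
female,48,16.1,1.771
female,60,18.2,2.002
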