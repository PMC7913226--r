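sex,height_cm,median_kg,sd_kg
male,65,7.4,0.592
male,70,8.4,0.672
male,75,9.3,0.744
male,80,10.4,0.832
male,85,11.7,0.936
male,90,12.9,1.032
male,95,14.1,1.128
male,100,15.4,1.232
male,105,16.8,1.344
male,110,18.4,1.472
male,115,20.3,1.624
male,120,22.4,1.792
male,125,24.7,1.976
female,65,7.2,0.576
female,70,8.2,0.656
female,75,9.1,0.728
female,80,10.2,0.816
female,85,11.5,0.92
female,90,12.7,1.016
female,95,13.9,1.112
female,100,15.2,1.216
female,105,16.8,1.344
female,110,18.6,1.488
female,115,20.7,1.656
female,120,23,1.84
female,125,25.4,2.032
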