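age_y,sex,bwt_kg,ht_cm,hematocrit,albumin_g_L,agp_g_L,gfr_L_h
0.25,male,6,61,0.35,38,0.45,0.453
1,male,9.6,75.7,0.36,40,0.55,1.4426
2,male,12.2,87.1,0.37,41,0.6,1.8407
3,male,14.3,96.1,0.375,41.5,0.65,2.0993
4,male,16.3,103.3,0.38,42,0.65,2.3259
5,male,18.3,110,0.38,42,0.7,2.5419
10,male,32,138,0.4,42,0.75,3.8757
15,male,56,167,0.44,42.5,0.8,5.9
30,male,73,176,0.47,42.5,0.8,7.2
80,male,73,176,0.47,42.5,0.8,7.2
0.25,female,6,61,0.35,38,0.45,0.4738
1,female,9.6,75.7,0.36,40,0.55,1.5088
2,female,12.2,87.1,0.37,41,0.6,1.9251
3,female,14.3,96.1,0.375,41.5,0.65,2.1955
4,female,16.3,103.3,0.38,42,0.65,2.4325
5,female,18.3,110,0.38,42,0.7,2.6584
10,female,32,138,0.4,42,0.75,4.0534
15,female,53,161,0.4,42.5,0.8,5.9207
30,female,60,163,0.42,42,0.8,6.5
80,female,60,163,0.42,42,0.8,6.5
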