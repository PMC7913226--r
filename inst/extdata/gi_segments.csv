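index,segment,transit_h,ph_fasted,ph_fed,fluid_mL,area_cm2,saef
1,stomach,0.25,1.3,5.0,50,280,0.1
2,duodenum,0.25,6.0,5.4,30,314,500
3,upper_jejunum,0.75,6.2,5.6,40,1100,500
4,lower_jejunum,0.75,6.4,6.0,40,942,500
5,upper_ileum,0.85,6.6,6.4,30,704,500
6,lower_ileum,0.85,6.9,6.8,30,653,500
7,caecum,2.5,5.9,5.9,10,154,2
8,colon_ascendens,4,6.2,6.2,10,314,2
9,colon_transversum,6,6.5,6.5,8,707,2
10,colon_descendens,6,6.8,6.8,8,471,2
11,colon_sigmoid,8,7.0,7.0,6,628,2
12,rectum,10,7.2,7.2,6,314,2
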