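tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,ra_alb,f_water,f_lipid,f_protein,ph_iw
adipose,0.135,0.017,0.853,0.0016,0.40,0.049,0.152,0.855,0.05,7.0
bone,0.100,0.346,0.017,0.0017,0.67,0.100,0.446,0.019,0.20,7.0
brain,0.162,0.620,0.039,0.0015,0.40,0.048,0.782,0.041,0.08,7.0
gut,0.282,0.475,0.038,0.0125,2.41,0.158,0.757,0.051,0.15,7.0
gonads,0.255,0.524,0.0066,0.0029,2.00,0.100,0.779,0.010,0.12,7.0
heart,0.320,0.456,0.014,0.0111,2.25,0.157,0.776,0.025,0.16,7.0
kidney,0.273,0.483,0.012,0.0242,5.03,0.130,0.756,0.036,0.16,7.0
liver,0.161,0.573,0.014,0.0240,4.56,0.086,0.734,0.038,0.18,7.0
lung,0.336,0.446,0.022,0.0128,3.91,0.212,0.782,0.035,0.13,7.0
muscle,0.118,0.630,0.010,0.0072,1.53,0.064,0.748,0.017,0.18,7.0
pancreas,0.120,0.664,0.041,0.0093,1.67,0.060,0.784,0.050,0.15,7.0
skin,0.382,0.291,0.060,0.0044,1.32,0.277,0.673,0.064,0.25,7.0
spleen,0.207,0.579,0.0077,0.0113,3.18,0.097,0.786,0.019,0.15,7.0
rbc,0.000,0.603,0.0017,0.0029,0.50,0.000,0.630,0.005,0.35,7.2
plasma,0.945,0.000,0.0023,0.0013,0.00,1.000,0.945,0.003,0.06,7.4
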