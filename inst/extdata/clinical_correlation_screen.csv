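feature,target,rho,p
V_PTV,mld_gy,0.747,0.000
V_PTV,v20_pct,0.693,0.000
V_PTV,v10_pct,0.731,0.000
V_PTV,start_deg,-0.033,0.717
V_PTV,stop_deg,-0.099,0.273
V_Lung,mld_gy,-0.196,0.029
V_Lung,v20_pct,-0.205,0.022
V_Lung,v10_pct,-0.235,0.008
V_Lung,start_deg,0.073,0.416
V_Lung,stop_deg,0.021,0.813
V_Heart,mld_gy,0.014,0.876
V_Heart,v20_pct,0.005,0.953
V_Heart,v10_pct,0.023,0.795
V_Heart,start_deg,-0.077,0.396
V_Heart,stop_deg,-0.124,0.168
D_PL,mld_gy,-0.508,0.000
D_PL,v20_pct,-0.519,0.000
D_PL,v10_pct,-0.467,0.000
D_PL,start_deg,0.182,0.042
D_PL,stop_deg,0.234,0.009
D_PH,mld_gy,-0.241,0.007
D_PH,v20_pct,-0.233,0.009
D_PH,v10_pct,-0.203,0.023
D_PH,start_deg,-0.432,0.000
D_PH,stop_deg,-0.412,0.000
OVZ_PL,mld_gy,0.654,0.000
OVZ_PL,v20_pct,0.639,0.000
OVZ_PL,v10_pct,0.583,0.000
OVZ_PL,start_deg,-0.033,0.713
OVZ_PL,stop_deg,-0.066,0.466
OVZ_PH,mld_gy,0.385,0.000
OVZ_PH,v20_pct,0.381,0.000
OVZ_PH,v10_pct,0.254,0.004
OVZ_PH,start_deg,-0.075,0.404
OVZ_PH,stop_deg,-0.061,0.496
X_PL,mld_gy,-0.098,0.277
X_PL,v20_pct,-0.154,0.087
X_PL,v10_pct,-0.075,0.405
X_PL,start_deg,0.762,0.000
X_PL,stop_deg,0.745,0.000
Y_PL,mld_gy,-0.100,0.265
Y_PL,v20_pct,-0.155,0.085
Y_PL,v10_pct,-0.074,0.415
Y_PL,start_deg,0.758,0.000
Y_PL,stop_deg,0.740,0.000
X_PH,mld_gy,-0.113,0.211
X_PH,v20_pct,-0.169,0.059
X_PH,v10_pct,-0.106,0.240
X_PH,start_deg,0.756,0.000
X_PH,stop_deg,0.729,0.000
Y_PH,mld_gy,-0.068,0.449
Y_PH,v20_pct,-0.114,0.207
Y_PH,v10_pct,-0.109,0.225
Y_PH,start_deg,-0.169,0.059
Y_PH,stop_deg,-0.078,0.385
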