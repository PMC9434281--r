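condition,C,H,N,S,O,HHV_MJ_per_kg,P_mg_per_L_day,RCO2_g_per_L_day
TAP + air,50.78,7.70,8.83,0.48,32.69,23.69,118.8,NA
TAP + nitrate,48.43,7.72,8.78,0.57,35.07,22.67,84.7,NA
TAP without acetic acid,43.17,6.55,7.0,0.96,43.28,18.42,68.3,NA
TAP + 0.1% glucose,54.55,7.09,9.72,0,28.64,22.14,98.1,NA
TAP + 0.2% glucose,45.99,6.53,8.30,0,39.18,18.08,110,NA
TAP control,49.00,8.67,8.54,0.42,29.34,20.69,101,NA
3NBBM control,47.19,7.49,7.75,0,37.57,19.01,65.4,NA
3NBBM + air,47.18,6.49,8.16,0.05,38.17,18.62,72.8,NA
3NBBM + 1% CO2,44.58,8.81,6.28,0,40.33,18.24,79.4,0.130
3NBBM + 2% CO2,49.34,7.04,8.64,0.69,34.98,20.42,74.2,0.134
3NBBM + 5% CO2,45.46,5.96,8.50,0.44,40.08,18.01,77,0.128
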