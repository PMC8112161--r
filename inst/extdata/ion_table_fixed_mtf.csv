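ion,symbol,E_init_MeV_u,sigma_wet_mm,sigma_wet_err,g_ph,g_ph_err,g_dt,g_dt_err,S_MC_MeV_mm3,S_MC_err,E_out_MeV_u,range_cm,mtf10_lp_cm
proton,1H,350.0,4.50,0.17,1.11,0.09,1.52,0.23,0.77,0.03,281.4,66.2,10.0
helium,4He,191.1,1.20,0.05,1.28,0.17,1.14,0.11,5.5,0.23,70.0,24.1,10.7
lithium,6Li,234.6,0.92,0.04,1.42,0.21,1.13,0.10,9.75,0.41,70.3,22.8,12.9
boron,10B,309.6,0.67,0.03,1.55,0.23,1.09,0.08,13.82,0.57,71.4,21.7,16.5
carbon,12C,343.1,0.61,0.03,1.61,0.24,1.08,0.07,15.47,0.61,70.9,21.4,18.0
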