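heating_rate_K_per_min,Ea_kJ_per_mol,Ea_se,ln_cA_per_s,ln_cA_se,n,n_se,m,m_se
5,71.5,2.5,9.7,0.5,3.38,0.04,0.4,0.04
10,99.9,3.3,15.6,0.7,3.61,0.06,-0.43,0.06
20,82.6,9.6,12.1,1.9,3.07,0.18,-0.18,0.18
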