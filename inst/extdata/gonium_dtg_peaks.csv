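heating_rate_K_per_min,T_p_K,rate_at_peak_per_min
5,592.72,0.031
10,593.62,0.063
20,606.99,0.119
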