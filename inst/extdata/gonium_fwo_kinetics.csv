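alpha,Ea_kJ_per_mol,R2,A_per_min,dH_kJ_per_mol,dG_kJ_per_mol,dS_kJ_per_mol_K
0.1,40.6,0.88,5.14e1,35.4,175.9,-0.227
0.15,60.3,0.93,5.22e3,55.2,171.8,-0.188
0.2,70.0,0.95,3.05e4,64.8,172.4,-0.173
0.25,89.6,0.96,2.06e6,84.5,170.3,-0.138
0.3,111.2,0.97,1.97e8,106.0,168.3,-0.101
0.35,123.1,0.97,1.85e9,118.0,168.8,-0.082
0.4,130.3,0.98,5.51e9,125.2,170.3,-0.073
0.45,136.9,0.98,1.37e10,131.7,172.2,-0.065
0.5,142.7,0.98,2.80e10,137.5,174.3,-0.059
0.55,147.3,0.99,4.36e10,142.1,176.6,-0.056
0.6,151.3,0.99,5.71e10,146.1,179.2,-0.053
0.65,156.6,0.99,9.12e10,151.5,182.2,-0.050
0.7,167.4,0.99,3.71e11,162.2,185.7,-0.038
0.75,185.6,0.99,5.12e12,180.4,190.3,-0.016
0.8,204.8,0.99,6.66e13,199.7,196.4,0.005
0.85,218.7,0.98,2.51e14,213.5,203.4,0.016
0.9,260.3,0.94,9.88e16,255.2,214.3,0.066
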