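side,index,eigenvalue_normalized,label,contribution
property,1,0.99118,Lip,0.00004
property,2,0.00641,Hyd,0.00000
property,3,0.00240,S_L,0.20595
property,4,0.00005,S_H,0.00534
property,5,0.00004,P_alpha,0.00004
property,6,0.00003,P_beta,0.00005
property,7,0.00002,P_c,0.00002
property,8,0.00001,Vol,0.78857
fragment,1,0.98873,Residue-1,0.12126
fragment,2,0.00300,Residue-2,0.12043
fragment,3,0.00249,Residue-3,0.1130
fragment,4,0.00213,Residue-4,0.09871
fragment,5,0.00106,Residue-5,0.1046
fragment,6,0.00094,Residue-6,0.10804
fragment,7,0.0007,Residue-7,0.11931
fragment,8,0.00058,Residue-8,0.10186
fragment,9,0.00037,Residue-9,0.11278
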