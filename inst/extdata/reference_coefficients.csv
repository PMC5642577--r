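side,index,label,coefficient
property,1,Lip,-0.02445
property,2,Hyd,0.19258
property,3,S_L,-0.00212
property,4,S_H,0.00348
property,5,P_alpha,0.15367
property,6,P_beta,0.07823
property,7,P_c,0.19764
property,8,Vol,0.00366
fragment,1,Residue-1,2.53268
fragment,2,Residue-2,8.36712
fragment,3,Residue-3,3.06856
fragment,4,Residue-4,-4.89559
fragment,5,Residue-5,3.12686
fragment,6,Residue-6,2.45367
fragment,7,Residue-7,1.24669
fragment,8,Residue-8,-3.50416
fragment,9,Residue-9,-3.79249
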