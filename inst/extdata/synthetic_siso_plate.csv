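well_id,gate_id,condition,replicate,od600,gfp,is_blank,plate
P1_BUFFER_I_YQR_PROXIMAL_c1_r1,BUFFER_I_YQR_PROXIMAL,I=0,1,0.507206600900745,1842.10691479122,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c1_r2,BUFFER_I_YQR_PROXIMAL,I=0,2,0.52835629704392,1979.82201874488,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c1_r3,BUFFER_I_YQR_PROXIMAL,I=0,3,0.553793887685808,2036.80633674509,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c1_r4,BUFFER_I_YQR_PROXIMAL,I=0,4,0.472232638868949,1732.68234964612,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c1_r5,BUFFER_I_YQR_PROXIMAL,I=0,5,0.518155436821689,2156.67737924386,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c1_r6,BUFFER_I_YQR_PROXIMAL,I=0,6,0.527987081354676,1773.05212298664,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r1,BUFFER_I_YQR_PROXIMAL,I=1,1,0.52857936060262,31911.367035562,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r2,BUFFER_I_YQR_PROXIMAL,I=1,2,0.564192114447964,37244.0996006209,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r3,BUFFER_I_YQR_PROXIMAL,I=1,3,0.540080912224391,34343.4216482257,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r4,BUFFER_I_YQR_PROXIMAL,I=1,4,0.53724020836157,32158.3776824043,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r5,BUFFER_I_YQR_PROXIMAL,I=1,5,0.549183382723531,29175.5247207164,FALSE,P1
P1_BUFFER_I_YQR_PROXIMAL_c2_r6,BUFFER_I_YQR_PROXIMAL,I=1,6,0.545317346200597,31556.0907766081,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r1,BUFFER_R_YQR_PROXIMAL,I=0,1,0.51156664445591,3181.01176143387,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r2,BUFFER_R_YQR_PROXIMAL,I=0,2,0.481291239504355,2513.36626576184,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r3,BUFFER_R_YQR_PROXIMAL,I=0,3,0.52429943153752,2547.60290341856,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r4,BUFFER_R_YQR_PROXIMAL,I=0,4,0.534007566176491,2795.57752133756,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r5,BUFFER_R_YQR_PROXIMAL,I=0,5,0.580674439272477,3616.24526737235,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c1_r6,BUFFER_R_YQR_PROXIMAL,I=0,6,0.579756579039367,3271.65946479371,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r1,BUFFER_R_YQR_PROXIMAL,I=1,1,0.55005600690868,35177.316764613,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r2,BUFFER_R_YQR_PROXIMAL,I=1,2,0.51936439557005,36023.0324439964,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r3,BUFFER_R_YQR_PROXIMAL,I=1,3,0.502330224105472,34760.6699063489,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r4,BUFFER_R_YQR_PROXIMAL,I=1,4,0.553441663761387,39100.1948857877,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r5,BUFFER_R_YQR_PROXIMAL,I=1,5,0.530252089100016,32528.7966105069,FALSE,P1
P1_BUFFER_R_YQR_PROXIMAL_c2_r6,BUFFER_R_YQR_PROXIMAL,I=1,6,0.51391379089078,36389.5921990617,FALSE,P1
P1_blank_r1,blank,blank,1,0.04,500,TRUE,P1
P1_blank_r2,blank,blank,2,0.04,500,TRUE,P1
P1_blank_r3,blank,blank,3,0.04,500,TRUE,P1
P1_blank_r4,blank,blank,4,0.04,500,TRUE,P1
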