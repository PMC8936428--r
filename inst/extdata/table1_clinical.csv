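subject_id,group,gender,age,stroke_type,lesion_side,tss_years,fma_t0,fma_tpost,fma_t6m,reported_recovery,training_intensity
S1,NG-AO,M,47,Hemo,left,2,20,24,26,good,1669
S2,NG-AO,M,65,Isch,right,5,23,33,,good,1306
S3,NG-AO,M,48,Hemo,right,1,17,25,25,good,1506
S4,NG-AO,M,68,Hemo,left,8,22,27,32,good,1453
S5,NG-AO,M,60,Isch,right,3,16,14,18,poor,1447
S6,NG-AO,M,61,Isch,left,11,22,24,24,poor,1657
S7,NG-AO,F,68,Isch,right,2,25,26,26,poor,1380
S8,NG-AO,F,48,Isch,right,1,36,41,48,good,1560
S9,NG-AO,M,53,Isch,left,1,41,36,40,poor,1289
S10,NG-AO,M,49,Isch,right,1,19,34,28,good,1382
S11,NG-AO,M,34,Isch,right,2,25,32,,good,1306
S13,NG-AO,M,59,"Isch, mild hemo",right,11,24,21,22,poor,1489
S14,nNG-text,M,42,Hemo,right,3,17,20,20,poor,1600
S15,nNG-text,M,57,Hemo,left,5,28,33,24,good,1600
S16,nNG-text,F,52,Hemo,left,3,34,34,37,poor,1600
S17,nNG-text,M,48,Hemo,right,1,34,37,35,poor,1600
S18,nNG-text,M,50,Isch,left,1,24,22,22,poor,1600
S19,nNG-text,M,57,Isch,right,6,13,23,20,good,1600
S20,nNG-text,M,50,Hemo,right,5,15,17,16,poor,1600
S21,nNG-text,M,51,Hemo,left,2,20,19,28,good,1600
S23,nNG-text,F,59,Isch,left,4,31,39,35,good,1600
S24,nNG-text,M,57,Isch,right,7,20,25,21,good,1600
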