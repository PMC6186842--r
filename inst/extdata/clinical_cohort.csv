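subject_id,group,lesion_side,age_band,gender,stroke_type,onset_years,lesion_locations,fma_pre,fma_post,fma_6mo
S1,guided,R,55-59,M,I,11,Brainstem,24,21,22
S2,guided,L,60-64,M,I,11,"PLIC, putamen",22,24,24
S3,guided,R,45-49,M,I,1,"MFG, SFG, precentral, supramarginal, SMA",19,34,28
S4,guided,L,65-69,M,H,8,"Insula, putamen, IFG, temporal pole",22,27,32
S5,guided,R,65-69,M,H,1,"Insula, ITG, IOG, putamen",13,16,27
S6,guided,R,45-49,M,H,0.67,"ITG, MTG, STG, MOG, angular, supramarginal",17,25,25
S7,guided,R,60-64,M,I,3,"Insula, putamen, rolandic operculum, IFG",16,14,18
S8,guided,L,50-54,M,I,1,"MFG, precentral, IFG, postcentral, insula, SFG",41,36,40
S9,guided,R,45-49,F,I,1,"Putamen, insula",36,41,48
S10,guided,L,45-49,M,H,2,,20,24,26
S11,guided,R,65-69,F,I,2,,25,26,26
S12,guided,R,65-69,M,I,5,,23,33,
S13,guided,R,30-34,M,I,2,"Insula, STG, IFG, putamen, rolandic operculum, temporal pole",25,32,
S14,sham,L,55-59,M,H,5,"Insula, IFG, putamen",28,33,24
S15,sham,R,55-59,M,I,7,"Insula, IFG, putamen, rolandic operculum, temporal pole",20,25,21
S16,sham,L,50-54,M,I,1,"Putamen, caudate nucleus",24,22,22
S17,sham,R,40-44,M,H,5,"Insula, rolandic operculum, IFG, STG, putamen, temporal pole",15,17,16
S18,sham,R,40-44,M,H,3,"Insula, MTG, STG, putamen, temporal pole, rolandic operculum",17,20,20
S19,sham,R,55-59,M,I,6,"Insula, rolandic operculum, IFG",13,23,20
S20,sham,L,50-54,F,H,3,"Insula, rolandic operculum, putamen",34,34,37
S21,sham,R,45-49,M,H,1,"Insula, putamen",34,37,35
S22,sham,L,55-59,M,H,2,,20,19,28
S23,sham,R,40-44,M,I,2,,33,31,50
S24,sham,L,55-59,F,I,4,,31,39,35
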