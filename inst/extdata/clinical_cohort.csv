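case_id,age_years,breed,weight_kg,staging,side,lobe,t_stage,n_stage,m_stage,diagnosis,grade,siln_metastasis,muc1_score,is_control
1,13,Mix,20,R5/T1N0M0,R,5,1,0,0,Carcinoma-solid type,3,0,0,FALSE
2,13,Italian Greyhound,30,R3/T1N0M0,R,3,1,0,0,Carcinoma-mixed type,1,0,1,FALSE
3,10,Mix,17,R4/T2N1M0,R,4,2,1,0,Carcinoma-simple (tubular),2,1,0,FALSE
4,12,Border Terrier,12,L3/T1N0M0,L,3,1,0,0,Carcinoma-mixed type,2,0,1,FALSE
5,12,Boxer,27,L5/T2N0M0,L,5,2,0,0,Adenosquamous carcinoma,3,0,0,FALSE
6,12,American Cocker Spaniel,12,L5/T2N1M1,L,5,2,1,1,Sarcoma,3,1,0,FALSE
7,11,Mix,23,R5/T1N0M0,R,5,1,0,0,Carcinoma-complex type,2,0,1,FALSE
8,8,Golden Retriever,27,L4/T1N0M0,L,4,1,0,0,Carcinoma-simple (tubulopapillary),2,0,2,FALSE
9,11,Mix,25,L5/T2N1M1,L,5,2,1,1,Carcinoma-simple (tubulopapillary),3,1,0,FALSE
10,13,Golden Retriever,28,L4/T1N0M0,L,4,1,0,0,Carcinoma-complex type,2,0,1,FALSE
11,10,Mix,12,R5/T1N0M0,R,5,1,0,0,Carcinoma-simple (tubulopapillary),2,0,1,FALSE
12,11,Yorkshire Terrier,6,L4/T1N1M0,L,4,1,1,0,Carcinoma-complex type,2,1,1,FALSE
13,8,American Cocker Spaniel,12,R5/T2N0M0,R,5,2,0,0,Carcinoma-solid type,3,0,1,FALSE
14,11,Cavalier King Charles Spaniel,8,L4/T2N1M0,L,4,2,1,0,Carcinoma-simple (tubulopapillary),3,1,3,FALSE
15,13,Border Terrier,7,L5/T1N0M0,L,5,1,0,0,Carcinoma-simple (tubular),3,0,1,FALSE
16,10,American Cocker Spaniel,22,R5/T1N1M0,R,5,1,1,0,Intraductal papillary carcinoma,1,1,0,FALSE
17,12,Mix,10,R3/T1N0M0,R,3,1,0,0,Carcinoma-mixed type,2,0,3,FALSE
18,4,Cocker Spaniel,20,R5/-,R,5,NA,NA,NA,Mild hyperplastic and fibrous reactions,NA,NA,2,TRUE
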