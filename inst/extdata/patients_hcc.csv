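patient_id,sex,age,previous_treatment,cirrhosis,n_lesions
1,M,59,"Surgery, TACE, ICI",yes,2
2,M,64,"RFA, ICI",yes,1
3,M,67,"Liver transplantation, radiotherapy, ICI",no,1
4,M,73,"Surgery, TACE, RFA, ICI",no,1
5,M,46,"Surgery, TACE, ICI",yes,3
6,M,61,"Surgery, TACE, RFA, ICI",yes,1
7,M,71,"Surgery, TACE, RFA, ICI",yes,1
8,M,50,"TACE, ICI",yes,2
9,M,38,"TACE, radiotherapy, ICI",yes,1
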