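patient_id,sex,age,previous_treatment,n_lesions
1,M,36,"RFA, ICI",3
2,M,42,"Surgery",3
3,M,70,"Surgery, radiotherapy, chemotherapy, gamma knife radiotherapy, ICI",1
4,M,61,"ICI",1
5,M,47,"Surgery, chemotherapy, RFA, ICI",3
6,F,73,"Radiotherapy, chemotherapy, gamma knife radiotherapy, RFA, ICI",1
7,M,49,"Surgery, chemotherapy, ICI",2
8,M,52,"Surgery, TACE, RFA, ICI",1
9,M,74,"ICI",1
10,F,44,"Surgery, chemotherapy, RFA, ICI",1
11,F,54,"Surgery, chemotherapy",1
12,M,62,"Surgery, chemotherapy, ICI",2
13,M,55,"TACE, chemotherapy, ICI",1
14,M,74,"Surgery, TACE, ICI",2
15,F,56,"Surgery, chemotherapy, TACE, RFA",2
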