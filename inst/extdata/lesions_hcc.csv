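patient_id,lesion_index,volume_cm3,suvmax
1,1,106.61,9.61
1,2,3.95,9.47
2,1,1.78,4.69
3,1,0.47,4.53
4,1,213.25,9.42
5,1,2.90,20.05
5,2,1.63,20.96
5,3,0.89,15.65
6,1,4.40,7.39
7,1,3.37,5.82
8,1,1.46,4.38
8,2,2.30,3.31
9,1,18.14,8.15
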