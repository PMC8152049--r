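patient_id,lesion_index,volume_cm3,suvmax
1,1,0.74,9.24
1,2,0.86,14.81
1,3,0.51,17.43
2,1,1.11,7.80
2,2,2.40,9.94
2,3,1.25,11.57
3,1,2.95,5.10
4,1,106.97,12.05
5,1,1.82,4.49
5,2,5.29,2.95
5,3,82.40,5.26
6,1,2.79,7.67
7,1,5.01,4.30
7,2,15.85,5.01
8,1,2.71,4.78
9,1,27.08,5.42
10,1,6.95,8.93
11,1,0.92,4.64
12,1,6.04,7.97
12,2,5.22,6.83
13,1,29.35,11.19
14,1,8.72,4.22
14,2,2.82,4.41
15,1,4.08,5.04
15,2,4.80,5.97
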