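patient_id,her2_cep17_ratio,her2_mean,cep17_mean,ve1max,ve2max,damax
P01,0.4,1.8,4.2,1,1,1
P02,0.5,2.1,4.4,1,1,1
P03,0.5,1.9,3.5,1,1,1
P04,0.9,3.0,3.4,1,1,1
P05,1.1,3.7,3.5,1,1,1
P06,1.3,4.2,3.3,1,1,1
P07,1.7,5.4,3.1,1,1,1
P08,1.8,5.7,3.2,1,1,1
P09,1.8,7.1,3.9,1,1,1
P10,2.1,2.7,1.3,1,1,1
P11,2.3,4.2,1.9,1,1,1
P12,2.4,3.2,1.3,1,1,1
P13,2.7,3.8,1.4,1,1,1
P14,4.6,12.6,2.8,1,1,1
P15,1.2,1.8,1.6,1,1,2
P16,1.3,2.3,1.8,1,1,2
P17,1.4,5.7,3.9,1,1,2
P18,1.5,6.7,4.5,1,1,2
P19,1.6,4.3,2.7,1,1,2
P20,1.6,5.3,3.3,1,1,2
P21,2.1,3.8,1.8,1,1,2
P22,4.5,4.5,1.0,1,1,2
P23,0.5,1.5,2.9,1,2,1
P24,1.0,2.1,2.1,1,2,2
P25,1.3,4.7,3.7,1,2,2
P26,1.4,4.1,2.8,1,2,2
P27,1.7,5.8,3.5,1,2,2
P28,2.0,5.4,2.8,1,2,2
P29,2.2,4.3,1.9,1,2,2
P30,1.0,4.9,4.7,2,2,2
P31,1.1,4.1,3.7,2,2,2
P32,1.2,3.0,2.4,2,2,2
P33,1.3,5.0,3.8,2,2,2
P34,1.4,3.3,2.4,2,2,2
P35,1.5,3.3,2.2,2,2,3
P36,3.4,11.3,3.4,2,2,3
P37,6.5,12.4,1.9,2,3,3
P38,1.7,9.0,5.2,3,2,3
P39,1.4,2.6,1.8,3,3,3
P40,1.5,4.6,3.1,3,3,3
P41,2.3,4.3,1.9,3,3,3
P42,4.5,4.5,1.0,3,3,3
P43,4.7,10.1,2.2,3,3,3
P44,4.9,11.2,2.3,3,3,3
P45,4.9,15.5,3.2,3,3,3
P46,5.4,13.8,2.6,3,3,3
P47,5.9,16.8,2.9,3,3,3
P48,6.5,20.4,3.2,3,3,3
P49,6.8,13.6,2.0,3,3,3
P50,7.2,22.7,3.2,3,3,3
P51,7.2,23.2,3.2,3,3,3
P52,8.3,22.0,2.7,3,3,3
P53,13.1,28.2,2.2,3,3,3
P54,13.3,38.5,2.9,3,3,3
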