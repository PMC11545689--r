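"temperature_C","males","females","intersex","rmu","study_id","clutch"
28,17,0,0,"EastPacific","PlayaGrande",""
29,9,1,0,"EastPacific","PlayaGrande",""
29.5,4,6,0,"EastPacific","PlayaGrande",""
30,1,15,0,"EastPacific","PlayaGrande",""
30.5,0,10,0,"EastPacific","PlayaGrande",""
31,0,12,0,"EastPacific","PlayaGrande",""
31.5,0,8,0,"EastPacific","PlayaGrande",""
32,0,19,0,"EastPacific","PlayaGrande",""
27.31,11,0,0,"WestPacific","Rantau Abang","1C"
28.9,9,0,0,"WestPacific","Rantau Abang","3C"
28.63,9,0,0,"WestPacific","Rantau Abang","4C"
30.43,0,5,0,"WestPacific","Rantau Abang","Oven"
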