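"temperature_C","males","females","intersex","rmu","study_id","clutch"
27.31,11,0,0,"WestPacific","Rantau Abang","1C"
28.9,9,0,0,"WestPacific","Rantau Abang","3C"
28.63,9,0,0,"WestPacific","Rantau Abang","4C"
30.43,0,5,0,"WestPacific","Rantau Abang","Oven"
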