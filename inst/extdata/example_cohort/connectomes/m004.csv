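"","L01","L02","L03","L04","R01","R02","R03","R04"
"L01",0,34.053,37.317,12.328,202.52,58.534,73.063,13.993
"L02",34.053,0,11.393,17.061,23.182,0,15.135,0.601
"L03",37.317,11.393,0,13.947,13.817,18.783,9.23,17.927
"L04",12.328,17.061,13.947,0,23.638,7.586,8.823,5.17
"R01",202.52,23.182,13.817,23.638,0,35.356,34.774,31.645
"R02",58.534,0,18.783,7.586,35.356,0,14.474,11.949
"R03",73.063,15.135,9.23,8.823,34.774,14.474,0,5.305
"R04",13.993,0.601,17.927,5.17,31.645,11.949,5.305,0
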