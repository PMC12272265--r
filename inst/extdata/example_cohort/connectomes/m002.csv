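"","L01","L02","L03","L04","R01","R02","R03","R04"
"L01",0,47.817,50.016,82.999,224.033,34.888,31.137,55.528
"L02",47.817,0,31.37,0,23.389,9.431,3.247,6.142
"L03",50.016,31.37,0,17.782,69.113,13.523,10.168,15.586
"L04",82.999,0,17.782,0,14.747,9.015,2.367,27.889
"R01",224.033,23.389,69.113,14.747,0,54.088,50.83,69.326
"R02",34.888,9.431,13.523,9.015,54.088,0,8.324,20.105
"R03",31.137,3.247,10.168,2.367,50.83,8.324,0,14.883
"R04",55.528,6.142,15.586,27.889,69.326,20.105,14.883,0
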