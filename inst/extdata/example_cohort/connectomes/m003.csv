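"","L01","L02","L03","L04","R01","R02","R03","R04"
"L01",0,44.633,43.128,12.462,182.852,39.376,46.078,26.807
"L02",44.633,0,2.685,8.897,29.429,25.849,8.498,11.965
"L03",43.128,2.685,0,8.653,32.442,19.36,14.966,16.736
"L04",12.462,8.897,8.653,0,33.411,30.486,11.647,4.261
"R01",182.852,29.429,32.442,33.411,0,46.788,42.427,8.295
"R02",39.376,25.849,19.36,30.486,46.788,0,9.255,7.312
"R03",46.078,8.498,14.966,11.647,42.427,9.255,0,13.323
"R04",26.807,11.965,16.736,4.261,8.295,7.312,13.323,0
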