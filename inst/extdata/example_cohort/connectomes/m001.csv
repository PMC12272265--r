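"","L01","L02","L03","L04","R01","R02","R03","R04"
"L01",0,53.984,54.443,25.31,57.149,133.438,8.15,104.31
"L02",53.984,0,9.303,9.034,19.65,6.075,4.266,10.643
"L03",54.443,9.303,0,3.219,48.524,5.308,12.94,12.255
"L04",25.31,9.034,3.219,0,71.23,18.795,12.38,19.636
"R01",57.149,19.65,48.524,71.23,0,55.979,47.626,8.417
"R02",133.438,6.075,5.308,18.795,55.979,0,20.445,5.137
"R03",8.15,4.266,12.94,12.38,47.626,20.445,0,1.262
"R04",104.31,10.643,12.255,19.636,8.417,5.137,1.262,0
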