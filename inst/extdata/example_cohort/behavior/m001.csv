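"time_platform","time_quadrant","metric1","metric2","metric3"
34.868,36.728,19.314,18.868,23.23
32.029,33.893,15.958,23.683,22.304
31.961,37.707,19.244,20.432,22.526
32.449,35.644,20.301,19.732,18.557
34.993,35.763,16.033,21.169,19.962
33.924,32.841,14.877,20.197,19.233
28.32,31.669,16.055,21.1,18.823
30.058,30.181,15.292,21.7,21.967
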