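"time_platform","time_quadrant","metric1","metric2","metric3"
38.438,44.732,18.79,18.478,19.987
38.276,45.512,16.751,20.37,18.974
36.428,41.076,19.695,18.599,20.824
40.296,39.569,20.384,18.803,18.39
39.605,40.479,21.81,15.632,18.511
38.228,34.754,20.933,15.403,16.462
34.137,33.659,19.097,18.353,21.926
31.173,32.701,18.41,17.732,16.305
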