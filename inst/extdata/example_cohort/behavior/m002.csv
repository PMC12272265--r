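"time_platform","time_quadrant","metric1","metric2","metric3"
30.965,35.922,17.994,20.015,24.42
34.39,28.427,17.551,21.384,23.211
36.949,33.145,22.033,19.229,19.525
28.954,33.332,14.467,18.257,21.363
38.31,30.543,16.151,19.117,22.966
32.557,37.677,15.278,19.571,20.319
27.347,31.424,17.312,22.02,19.271
28.79,31.522,16.318,19.853,19.988
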