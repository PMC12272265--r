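"time_platform","time_quadrant","metric1","metric2","metric3"
44.048,40.267,20.495,17.541,19.058
44.934,46.611,23.442,18.116,17.273
46.578,39.552,19.666,16.482,21.267
40.314,41.946,19.277,16.6,17.212
37.568,41.229,20.894,18.217,19.744
41.637,44.443,19.016,15.626,17.732
41.54,40.891,21.757,16.618,16.781
33.369,39.906,18.007,20.339,16.398
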