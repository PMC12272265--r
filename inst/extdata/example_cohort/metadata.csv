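"id","age_days","sex","diet","apoe","nos2"
"m001",427.35,"M","HFD","APOE4","mNos2"
"m002",419.327,"F","CTRL","APOE3","hNOS2"
"m003",505.316,"F","CTRL","APOE4","mNos2"
"m004",527.527,"M","CTRL","APOE3","hNOS2"
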