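"outcome","group","mean","sd","n"
"cost","medium",1530,880,59
"cost","high",1930,1070,19
"utility","medium",0.81,0.12,59
"utility","high",0.78,0.21,19
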