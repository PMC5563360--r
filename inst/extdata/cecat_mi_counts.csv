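"from","to","count"
"medium","mi",39
"medium","no_mi",1678
"high","mi",62
"high","no_mi",2097
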