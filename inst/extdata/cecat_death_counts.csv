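"from","to","count"
"medium","dead",126
"medium","alive",445
"high","dead",259
"high","alive",495
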