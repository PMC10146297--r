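"","0","1-10","11-100","101-400",">400"
"0",27,4,1,0,0
"1-10",0,17,0,0,0
"11-100",0,5,21,1,0
"101-400",0,0,0,16,3
">400",0,0,0,2,16
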