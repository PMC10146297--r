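"","0","1-10","11-100","101-400",">400"
"0",46,5,0,0,0
"1-10",0,15,6,0,0
"11-100",0,1,60,3,0
"101-400",0,0,0,39,0
">400",0,0,0,1,22
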