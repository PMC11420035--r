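predicted,MO,TTH,PM,PTTH
MO,128,0,0,0
TTH,0,69,0,0
PM,3,0,73,0
PTTH,0,1,0,40
Others,0,0,7,4
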