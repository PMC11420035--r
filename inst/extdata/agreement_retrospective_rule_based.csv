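predicted,MO,TTH,PM,PTTH
MO,126,0,0,0
TTH,0,64,0,0
PM,5,3,69,0
PTTH,0,2,0,34
Others,0,1,11,10
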