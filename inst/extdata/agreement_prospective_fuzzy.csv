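predicted,MO,TTH,PM,PTTH
MO,164,4,3,0
TTH,5,106,5,2
PM,5,0,53,1
PTTH,1,3,1,21
Others,4,2,0,0
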