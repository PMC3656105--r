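subject,group,min_tp
C1,Control,170
C6,Control,240
C11,Control,140
C13,Control,170
C14,Control,250
C16,Control,270
A7,SCI,240
A10,SCI,140
A14,SCI,140
A15,SCI,170
B3,SCI,180
B5,SCI,140
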