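id,cvp,el,rl,fm,gm,vmi
ASD001,28,14,18,22,31,17
ASD002,21,9,12,18,26,13
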