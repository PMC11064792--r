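id,item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12,item13,item14,item15
ASD001,2,2.5,3,2,2,1.5,2,2.5,2,2,3,2,1.5,2,2
ASD002,3,3.5,3,2.5,3,2.5,3,2.5,2,3,3,2.5,2,3,2.5
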