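"","ADAM8","ADAM10","ADAM12","ADAM17"
"S1",1,0.1,0.05,0.2
"S2",0.15,1.2,0.1,0.05
"S3",0.05,0.8,0.3,0.1
"S4",0.1,0.05,1.1,0.15
"S5",0.2,0.15,0.7,0.4
"S6",0.05,0.1,0.15,1
"S7",0.3,0.25,0.2,0.6
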