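seq	nnfold	rnafold
GGCGCAACUCCAGUGCCAAAUGGCGCUUAG	-7.08	-8.70
AUGGCUAGCGGAUCGAAGCUUCGAUCCGGA	-10.53	-12.70
ACGUACGUACGUACGUACGUACGUACGUAC	-17.58	-18.10
GGGGGGAAAAACCCCCC	-10.60	-11.90
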