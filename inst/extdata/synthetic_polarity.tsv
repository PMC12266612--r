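pos_01	1
pos_02	1
pos_03	1
pos_04	1
pos_05	1
pos_06	1
neg_01	-1
neg_02	-1
neg_03	-1
neg_04	-1
neg_05	-1
neg_06	-1
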