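deg_01	0.5
deg_02	1.5
deg_03	2
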