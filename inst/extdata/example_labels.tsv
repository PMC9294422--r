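id	label	species
syn_00001	0	example
syn_00002	1	example
syn_00003	1	example
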