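syn_chl_001	chl
syn_chl_002	chl
syn_mit_001	mit
syn_mit_002	mit
syn_nuc_001	nuc
syn_nuc_002	nuc
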