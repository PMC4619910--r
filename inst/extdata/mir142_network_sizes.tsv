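network	n_nodes	n_edges
mir_null	57	217
mir_142	52	158
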