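gene_id	direction
g00001	up
g00002	up
g00005	up
g00003	down
g00006	down
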