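HYPOXIA_RESPONSE_UP	synthetic example set	g00001	g00002	g00004
HYPOXIA_RESPONSE_DN	synthetic example set	g00003	g00006
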