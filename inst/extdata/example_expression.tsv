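gene_id	s1	s2	s3	s4
g00001	7.10	6.90	7.30	7.00
g00002	8.25	8.40	8.10	8.30
g00003	5.60	5.80	5.50	5.70
g00004	6.95	7.05	7.20	6.80
g00005	9.10	8.90	9.30	9.00
g00006	6.40	6.60	6.20	6.50
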