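sample_id	study_id	group
s1	study1	case
s2	study1	control
s3	study1	case
s4	study1	control
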