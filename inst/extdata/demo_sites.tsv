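species	tf_id	site_id	sequence
demo	TFdemo	s1	ACCTAAGCTG
demo	TFdemo	s2	ATTACACCAAGTACC
demo	TFdemo	s3	GGAATTTCCTGTTGATCC
demo	TFdemo	s4	CTAAAGGACGTCACATTGC
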