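model	Setting1	Setting2	Setting3
M1	-3797	-2547	-3003
M2	42132	212173	21300
M3	41911	210996	21183
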