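setting	dic_causal	dic_reverse
S1	-10480	-4161
S2	-11074	-358
S3	-4242	-3661
S4	-2203	1115
S5	3004	5214
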