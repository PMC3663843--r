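model	Setting1	Setting2	Setting3
M4	43347	218230	21883
M5	41915	211254	21189
M6	81	-1549	689
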