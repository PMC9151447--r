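variable	category	AFR	EUR
total	total	65	544
stage	I	9	96
stage	II	20	195
stage	III	22	154
stage	IV	13	77
stage	Missing	2	21
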