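category	tested	confirmed	germline
shared	62	62	8
specific	51	41	0
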