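metric	observed	n_total	null_median	tail_count	n_sims
genic_breakpoints	3496	7676	3323	1	10000
cancer_genes	46	985	26	2	10000
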