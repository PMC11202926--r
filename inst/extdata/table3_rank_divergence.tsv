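rank	max	min	mean	se
within_species	3.29	0	0.63	0.2
within_genus	7.27	0	1.68	0.33
within_family	10.91	1.14	3.98	0.56
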