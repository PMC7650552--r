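cluster	observed_ppi	null_mean	null_sd
2	68	35.76	10.90
3	3	3.21	2.27
4	64	69.79	15.47
5	25	39.87	11.27
6	6	12.33	5.30
7	27	14.84	6.05
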