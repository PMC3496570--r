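snp_id	freq_elite	freq_average	afd_reported
ARS-BFGL-NGS-56327	0.65	0.29	0.36
ARS-BFGL-NGS-17376	0.64	0.27	0.37
BFGL-NGS-117985	0.53	0.05	0.48
ARS-BFGL-NGS-1096	0.53	0.02	0.51
BTB-01654826	0.48	0.40	0.08
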