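class	n_cds	n_reads
Secreted	2228	104622738
Housekeeping	7281	103850665
Transposable element	560	2092706
Viral	47	990621
Unknown	1072	2199892
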