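accession	cds_start	cds_end	utr3_start	utr3_end
SIMG001	1	300	301	716
SIMG002	1	312	313	762
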