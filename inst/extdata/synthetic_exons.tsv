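exon_id	gene_id	chrom	start	end	strand
SYNGENE1_ex2	SYNGENE1	chrS	301	498	+
SYNGENE2_exA	SYNGENE2	chrS	1301	1400	+
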