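chrS	synthetic	gene	101	800	.	+	.	gene_id "SYNGENE1";
chrS	synthetic	transcript	101	700	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	exon	101	200	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	exon	301	498	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	exon	601	700	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	CDS	151	200	.	+	0	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	CDS	301	498	.	+	1	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	CDS	601	652	.	+	1	gene_id "SYNGENE1"; transcript_id "TX_INC";
chrS	synthetic	transcript	101	700	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_STRICT";
chrS	synthetic	exon	101	200	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_STRICT";
chrS	synthetic	exon	601	700	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_STRICT";
chrS	synthetic	CDS	151	200	.	+	0	gene_id "SYNGENE1"; transcript_id "TX_SKIP_STRICT";
chrS	synthetic	CDS	601	652	.	+	1	gene_id "SYNGENE1"; transcript_id "TX_SKIP_STRICT";
chrS	synthetic	transcript	1	800	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_ALT";
chrS	synthetic	exon	1	200	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_ALT";
chrS	synthetic	exon	601	800	.	+	.	gene_id "SYNGENE1"; transcript_id "TX_SKIP_ALT";
chrS	synthetic	CDS	151	200	.	+	0	gene_id "SYNGENE1"; transcript_id "TX_SKIP_ALT";
chrS	synthetic	CDS	601	697	.	+	1	gene_id "SYNGENE1"; transcript_id "TX_SKIP_ALT";
chrS	synthetic	gene	1101	1700	.	+	.	gene_id "SYNGENE2";
chrS	synthetic	transcript	1101	1700	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	exon	1101	1200	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	exon	1301	1400	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	exon	1601	1700	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	CDS	1151	1200	.	+	0	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	CDS	1301	1400	.	+	1	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	CDS	1601	1651	.	+	0	gene_id "SYNGENE2"; transcript_id "TX_MXE_A";
chrS	synthetic	transcript	1101	1700	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	exon	1101	1200	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	exon	1451	1550	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	exon	1601	1700	.	+	.	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	CDS	1151	1200	.	+	0	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	CDS	1451	1550	.	+	1	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
chrS	synthetic	CDS	1601	1651	.	+	0	gene_id "SYNGENE2"; transcript_id "TX_MXE_B";
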