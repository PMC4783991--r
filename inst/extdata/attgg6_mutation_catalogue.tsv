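mu_id	kind	ref_start	ref_end	length	intron_index	detail	description
Mu1	insertion	155	155	2	NA	NA	two-base insertion in exon 1
Mu2	deletion	437	644	208	NA	NA	208-base deletion from intron 2 to exon 4
Mu3	insertion	481	481	1	NA	NA	one-base insertion in exon 3
Mu4	insertion	1007	1007	1	NA	NA	one-base insertion in exon 6
Mu5	insertion	1158	1158	2	NA	NA	two-base insertion in exon 7
Mu6	deletion	1739	1742	4	NA	NA	four-base deletion in exon 9
Mu7	deletion	1804	1817	14	NA	NA	14-base deletion in exon 9
Mu8	deletion	2111	2127	17	NA	NA	17-base deletion from intron 10 into exon 11
Mu9	splice_acceptor_sub	2113	2114	2	10	AT	3' splice border of intron 10 mutated from AG to AT
Mu10	splice_acceptor_sub	2113	2114	2	10	GG	3' splice border of intron 10 mutated from AG to GG
Mu11	insertion	2121	2121	1	NA	NA	one-base insertion in exon 11 near the intron-10 3' border
Mu12	deletion	2311	2327	17	NA	NA	17-base deletion in exon 12
Mu13	deletion	2348	2348	1	NA	NA	one-base deletion in exon 12, 20 nucleotides after Mu12
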