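# hg38 chromosome-arm spans (1-based inclusive, approximate centromere
# boundaries) for the arms used in arm-level event calling.
chrom	start	end	name
chr1	1	123400000	1p
chr1	123400001	248956422	1q
chr3	1	90900000	3p
chr3	90900001	198295559	3q
chr4	1	50000000	4p
chr4	50000001	190214555	4q
chr6	1	59800000	6p
chr6	59800001	170805979	6q
chr10	1	39800000	10p
chr10	39800001	133797422	10q
chr13	17700000	114364328	13q
chr17	1	25100000	17p
chr17	25100001	83257441	17q
chrX	1	61000000	Xp
chrX	61000001	156040895	Xq
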