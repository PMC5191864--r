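# Mitochondrial region map, 1-based inclusive rCRS (NC_012920) coordinates.
# The control region wraps the origin and is stored as two segments sharing
# one name. codon_offset is the reading-frame offset at `start` (heavy-strand
# orientation) and is defined for protein_coding records only.
name	region_class	start	end	strand	codon_offset
MT-TF	tRNA	577	647	heavy	NA
MT-RNR1	rRNA	648	1601	heavy	NA
MT-TV	tRNA	1602	1670	heavy	NA
MT-RNR2	rRNA	1671	3229	heavy	NA
MT-TL1	tRNA	3230	3304	heavy	NA
MT-ND1	protein_coding	3307	4262	heavy	0
MT-TI	tRNA	4263	4331	heavy	NA
MT-TQ	tRNA	4329	4400	light	NA
MT-TM	tRNA	4402	4469	heavy	NA
MT-ND2	protein_coding	4470	5511	heavy	0
MT-TW	tRNA	5512	5579	heavy	NA
MT-TA	tRNA	5587	5655	light	NA
MT-TN	tRNA	5657	5729	light	NA
MT-TC	tRNA	5761	5826	light	NA
MT-TY	tRNA	5826	5891	light	NA
MT-CO1	protein_coding	5904	7445	heavy	0
MT-TS1	tRNA	7446	7514	light	NA
MT-TD	tRNA	7518	7585	heavy	NA
MT-CO2	protein_coding	7586	8269	heavy	0
MT-TK	tRNA	8295	8364	heavy	NA
MT-ATP8	protein_coding	8366	8572	heavy	0
MT-ATP6	protein_coding	8527	9207	heavy	0
MT-CO3	protein_coding	9207	9990	heavy	0
MT-TG	tRNA	9991	10058	heavy	NA
MT-ND3	protein_coding	10059	10404	heavy	0
MT-TR	tRNA	10405	10469	heavy	NA
MT-ND4L	protein_coding	10470	10766	heavy	0
MT-ND4	protein_coding	10760	12137	heavy	0
MT-TH	tRNA	12138	12206	heavy	NA
MT-TS2	tRNA	12207	12265	heavy	NA
MT-TL2	tRNA	12266	12336	heavy	NA
MT-ND5	protein_coding	12337	14148	heavy	0
MT-ND6	protein_coding	14149	14673	light	0
MT-TE	tRNA	14674	14742	light	NA
MT-CYB	protein_coding	14747	15887	heavy	0
MT-TT	tRNA	15888	15953	heavy	NA
MT-TP	tRNA	15956	16023	light	NA
D-loop	control_region	16024	16569	heavy	NA
D-loop	control_region	1	576	heavy	NA
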