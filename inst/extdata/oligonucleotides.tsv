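oligo_id	sequence	application
W1746	TCAACTGCAGAGAGAGAAAAATAATGCGGTGC	intron RIG fragment amplification
W1747	AGCCACTAGTTTAGGAATGACTTTCCAGTC	intron RIG fragment amplification
IDT1544	CTAGACTAGTTAACTCAGCAGCTCTCTGAAATTC	intron-containing ltrB gene amplification
IDT1545	ACATGCATGCTTATAGTATTTTTCCTTTATTTTC	intron-containing ltrB gene amplification
IDT2014	TCTTTTTCCTTTTATTTCAAATCCAGA	Y21F mutagenesis
IDT2015	TTTGAAATAAAAGGAAAAAGATTTGTG	Y21F mutagenesis
IDT2016	TCTTTTTCCTGCTATTTCAAATCCAGA	Y21A mutagenesis
IDT2017	TTTGAAATAGCAGGAAAAAGATTTGTG	Y21A mutagenesis
IDT2018	CTCATCCAACGATTTTCTCCTGA	S117R mutagenesis
IDT2019	AGGAGAAAATCGTTGGATGAGGT	S117R mutagenesis
IDT2020	CTCATCCAAGCATTTTCTCCTGA	S117A mutagenesis
IDT2021	AGGAGAAAATGCTTGGATGAGGT	S117A mutagenesis
IDT2022	TGAACACATCCGTAACCATATCATT	H159R mutagenesis
IDT2023	GTTACGGATGTGTTCACGATCG	H159R mutagenesis
IDT2024	TGAACACATCGCTAACCATATCATT	H159A mutagenesis
IDT2025	GTTAGCGATGTGTTCACGATCG	H159A mutagenesis
IDT2026	ACATCCATAACCGTATCATTTTTAATT	H161R mutagenesis
IDT2027	AAATGATACGGTTATGGATGTGTTCA	H161R mutagenesis
IDT2028	ACATCCATAACGCTATCATTTTTAATT	H161A mutagenesis
IDT2029	AAATGATAGCGTTATGGATGTGTTCA	H161A mutagenesis
IDT3381	TGAGAGCTCAAGGAGGTTAATCTAATGCATCATCATCATCACCACGTTTACACAAAACACATTATTGTTC	ltrB gene amplification for expression cloning
IDT3277	ACAGCATGCTTATAGTATTTTTCCTTTATTTTCTTCAAG	ltrB gene amplification for expression cloning
IDT3509	TCTCACAAATCTTTTTCCTGCTATTTCAAATCCAGACAAGAC	Y21A direct mutagenesis
IDT3510	GTCTTGTCTGGATTTGAAATAGCAGGAAAAAGATTTGTGAGAT	Y21A direct mutagenesis
IDT3584	CGATCGACTAGTGCTATCCATTTCTTAAATTCCGTAAGATGCTATCATCTTACTATGCTTGCAAAAGGTCAAGGAAGTACATAGCATGCCAGTAGA	pRS01 oriT; activity assay; nic determination
IDT3585	CTACTGGCATGCTATGTACTTCCTTGACCTTTTGCAAGCATAGTAAGATGATAGCATCTTACGGAATTTAAGAAATGGATAGCACTAGTCGATCGA	pRS01 oriT; activity assay; nic determination
IDT3582	CGATCGACTAGTGCTAGAATGACTTACGCGCACCGAAAGGTCGTATTGTCTATAGCCAGGCGAATTCGTAGTGTTACTACATAGCATGCCAGTAGA	R388 oriT; activity assay
IDT3583	CTACTGGCATGCTATGTAGTAACACTACGAATTCGCCTGGCTATAGACAATACGACCTTTCGGTGCGCGTAAGTCATTCTAGCACTAGTCGATCGA	R388 oriT; activity assay
IDT3492	GGGCCCGACGTCGCA	nic determination; cleavage mapping
IDT3751	CTTTCTGATTACAGTGATCTTAAAGG	glnP locus cloning
IDT3752	GATAAAGATTGTTAATACTAAGAGCGG	glnP locus cloning; cleavage mapping
IDT3822	GAAGCAGTTCCGTTTTTAGCACC	glnP locus cleavage mapping
P7A	GATCGGAAGATCGTATGCCGTCTTCTGCTTG	sequencing adapter
P5A	ACACTCTTTCCCTACACGACGCTCTTCCGATCT	sequencing adapter
P7	CAAGCAGAAGACGGCATACGAGCTCTTCCGATCT	P7-specific primer
P-SJ	CAGCTCTCTTGGGTCTTTAAATGGAGTGTCTTCTTCCC	splice-junction specific primer
P5i1	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCTATCACGNNNNNNCAAGGCGGTACCTCCCTACTTCAC	library amplification, barcode ATCACG (control library)
P5i2	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCTTTAGGCNNNNNNCAAGGCGGTACCTCCCTACTTCAC	library amplification, barcode TTAGGC (pRS01 library)
P5i3	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCTCAGATCNNNNNNCAAGGCGGTACCTCCCTACTTCAC	library amplification, barcode CAGATC (relaxase library)
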