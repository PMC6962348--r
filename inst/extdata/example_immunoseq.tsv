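nucleotide	amino_acid	v_gene	v_family	reads	productive_frequency
TGTCCAAGGATGCAAGTCTCACTATTGTACATATATTACCCCATGTTC	CPRMQVSLLYIYYPMF	TRBV1	TRBV1	168	0.28
TGCATCAACAGGGGCGATATTTGGGTAAGTGAGATAGCCGTTAATGCGCGGTTC	CINRGDIWVSEIAVNARF	TRBV11	TRBV11	85	0.141667
TGCGTAGACATGGACCGATGGGACATGGACCCCCATTTC	CVDMDRWDMDPHF	unresolved	TRBV18	57	0.095
TGCGAGTCCAAAGGGTGCTCGAAGAAAACTGGGTTC	CESKGCSKKTGF	TRBV2	TRBV2	43	0.0716667
TGTCTTTTCCCGCCGGAGAAAGTTGCCTTC	CLFPPEKVAF	TRBV5	TRBV5	35	0.0583333
TGTCCGCATATGGAAAGGCCACTACACCAAAGAAATTCGTTC	CPHMERPLHQRNSF	TRBV11	TRBV11	29	0.0483333
TGTTGGAAGGAGCAAATGGACTGCGGCTATGGTAGGTTCATCTTC	CWKEQMDCGYGRFIF	TRBV5	TRBV5	25	0.0416667
TGCGTGGATATGGACCGTTGGGATATGGATCCTCACTTT	CVDMDRWDMDPHF	TRBV18	TRBV18	22	0.0366667
TGCTGGAAGGAGTATTACTTCGAGCTGTTCATGACGTTT	CWKEYYFELFMTF	TRBV34	TRBV34	19	0.0316667
TGTAACACGACGCGTCGGGCGAGTATGTCGGGGTGCCTCGTAATTTGCTACCCTTTT	CNTTRRASMSGCLVICYPF	TRBV1	TRBV1	17	0.0283333
TGTTGGGACACCTGCCTTGTGTGTTGGAAATGGGCGCCCTTTTTC	CWDTCLVCWKWAPFF	TRBV2	TRBV2	16	0.0266667
TGTCTATTTCCACCGGAGAAAGTGGCATTC	CLFPPEKVAF	TRBV5	TRBV5	15	0.025
TGTCGGTGCTGCACTTGGCGAACGGCATGCCTGTCCTTT	CRCCTWRTACLSF	TRBV2	TRBV2	13	0.0216667
TGTATGCAAAGTTGCCACCATCAAATGTTTCACACTCACGTTTTT	CMQSCHHQMFHTHVF	TRBV6	TRBV6	13	0.0216667
TGCATCGAATGCGGCGAGAAATATTACATTCAGTGTGAATTC	CIECGEKYYIQCEF	TRBV2	TRBV2	12	0.02
TGCCATAAGTACGCACCACTCATGGCTGATAAAGGTAAGTCATTC	CHKYAPLMADKGKSF	TRBV1	TRBV1	11	0.0183333
TGTCATAGTGCACCACACGGGCAACATTGCTCTAAACGAATCTTC	CHSAPHGQHCSKRIF	TRBV3	TRBV3	10	0.0166667
TGTTTCCACTGCGAAACGGAGGACAGTAGCCACTATTTC	CFHCETEDSSHYF	TRBV25	TRBV25	10	0.0166667
TGTGCCAGCAGCTT		TRBV1	TRBV1	4	null
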