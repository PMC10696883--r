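ligand_id	sequence	kd_uM	dH	minus_TdS	dG
Pos_Ctrl	GGGCAAAACCGGTTTTGCGG	0.11	-93.7	55.8	-37.9
Pos_Ctrl_V1	GGGCAAAACCGATTTTGCGG	3.40	-117.0	87.7	-29.7
Pos_Ctrl_V2	GGGCAAAACCGCTTTTGCGG	1.54	-81.7	50.0	-31.5
Pos_Ctrl_V3	GGGCAAAACCGTTTTTGCGG	4.35	-55.5	26.4	-29.1
Novel	AGGTTTTTCCACTTTGGGGC	0.18	-52.6	16.0	-36.6
Novel_V1	AGGTTTTTCCAATTTGGGGC	NBD	NA	NA	NA
Novel_V2	AGGTTTTTCCAGTTTGGGGC	0.21	-103.1	62.4	-41.0
Novel_V3	AGGTTTTTCCATTTTGGGGC	NBD	NA	NA	NA
Neg_Ctrl	GCAAAAAGGAGTCATTGGTG	NBD	NA	NA	NA
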