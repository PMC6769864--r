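level	label	parent	position	ref	alt
clade	I	NA	10	A	G
clade	I	NA	30	A	G
clade	I	NA	50	A	G
clade	I	NA	70	A	G
clade	I	NA	90	A	G
clade	I	NA	110	A	G
clade	I	NA	130	A	G
clade	I	NA	150	A	G
clade	I	NA	170	A	G
clade	I	NA	190	A	G
clade	I	NA	210	A	G
clade	I	NA	230	A	G
clade	I	NA	250	A	G
clade	I	NA	270	A	G
clade	I	NA	290	A	G
clade	I	NA	310	A	G
clade	I	NA	330	A	G
clade	I	NA	350	A	G
clade	I	NA	370	A	G
clade	I	NA	390	A	G
haplogroup	T1	T	15	A	G
haplogroup	T1	T	55	A	G
haplogroup	T1	T	95	A	G
haplogroup	T1	T	135	A	G
haplogroup	T2	T	25	A	G
haplogroup	T2	T	65	A	G
haplogroup	T2	T	105	A	G
haplogroup	T4	T	35	A	G
haplogroup	T4	T	75	A	G
haplogroup	T6	T	45	A	G
haplogroup	T6	T	85	A	G
haplogroup	T6	T	125	A	G
haplogroup	T6	T	165	A	G
haplogroup	I2	I	155	A	G
haplogroup	I2	I	195	A	G
haplogroup	I2	I	235	A	G
subhaplogroup	I1a	I1	205	A	G
subhaplogroup	I1a	I1	245	A	G
haplogroup	T3	T	NA	NA	NA
haplogroup	I1	I	NA	NA	NA
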