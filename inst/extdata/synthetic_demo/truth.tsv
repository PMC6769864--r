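sample_id	haplogroup	subhaplogroup	template	n_private	private_positions
DM001	T1	NA	tmpl001	0	
DM002	T1	NA	tmpl002	1	344
DM003	T1	NA	tmpl003	1	229
DM004	T1	NA	tmpl004	1	338
DM005	T2	NA	tmpl005	1	332
DM006	T2	NA	tmpl006	1	349
DM007	T3	NA	tmpl007	1	345
DM008	T3	NA	tmpl008	0	
DM009	T3	NA	tmpl009	1	356
DM010	T3	NA	tmpl010	2	333;344
DM011	T3	NA	tmpl011	2	326;367
DM012	T4	NA	tmpl012	1	152
DM013	T4	NA	tmpl013	0	
DM014	T6	NA	tmpl014	0	
DM015	T6	NA	tmpl015	1	336
DM016	I1	I1a	tmpl016	1	361
DM017	I1	I1a	tmpl017	2	320;321
DM018	I1	I1a	tmpl018	0	
DM019	I1	NA	tmpl019	0	
DM020	I1	NA	tmpl020	1	305
DM021	I1	NA	tmpl021	2	335;362
DM022	I2	NA	tmpl022	0	
DM023	I2	NA	tmpl023	2	321;334
DM024	I2	NA	tmpl024	1	362
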