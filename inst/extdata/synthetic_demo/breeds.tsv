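DM001	Yunling
DM002	Yunling
DM003	Yunling
DM004	Yunling
DM005	Yunling
DM006	Yunling
DM007	Yunling
DM008	Yunling
DM009	Yunling
DM010	Yunling
DM011	Yunling
DM012	Yunling
DM013	Yunling
DM014	Yunling
DM015	Yunling
DM016	Yunling
DM017	Yunling
DM018	Yunling
DM019	Yunling
DM020	Yunling
DM021	Yunling
DM022	Yunling
DM023	Yunling
DM024	Yunling
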