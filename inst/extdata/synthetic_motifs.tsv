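motif_id	pattern	site_offset	max_repeat	skip_flag	kinase_accessions	description
SYN001	[RK](2)-x-[ST]	2	0	FALSE	KIN001;KIN002	synthetic basophilic serine/threonine site (fixture, not curated content)
SYN002	[ST]-x-[RK]	0	0	FALSE	KIN003	synthetic PKC-shaped site (fixture)
SYN003	[ST]-x(2)-[DE]	0	0	FALSE	KIN004;KIN005	synthetic acidophilic CK2-shaped site (fixture)
SYN004	[RK]-x(2)-[DE]-x(3)-Y	4	0	FALSE	KIN006	synthetic tyrosine site (fixture)
SYN005	H-x-[ST]	0	2	TRUE	KIN007	synthetic skip-flagged histidine-adjacent site (fixture)
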