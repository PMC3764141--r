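# Base-triple census for the eleven reference riboswitch structures.
# One row per published triple: residue tokens are base + author number;
# wc_members marks which two residues form a canonical Watson-Crick pair
# ("2-3" = second and third residue; empty = none).  Element labels use
# ASCII hyphens (J1-2).
pdb_id	res1	res2	res3	wc_members	context	riboswitch_class
1y26	A23	G46	C53	2-3	Interaction between junctions (J1-2 & J2-3)	Purine
1y26	A66	G38	C60	2-3	Hairpin loop - hairpin loop interaction (L2 & L3)	Purine
2gis	A62	G23	C29	2-3	Helix - junction interaction (P2b & J3-4)	SAM-I
2qwy	G8	G42	C23	2-3	Helix - hairpin loop interaction	SAM-II
2qwy	U11	A45	U21	2-3	Helix - hairpin loop interaction (P2b & L1)	SAM-II
2qwy	U12	A46	U20	2-3	Helix - hairpin loop interaction (P2b & L1)	SAM-II
3e5c	A27	G71	G66		Helix - junction interaction (P2 & J3-2)	SAM-III
3e5c	A73	G90	C25	2-3	Helix - junction interaction (P1 & J2-4)	SAM-III
3fu2	A16	G11	C31	2-3	Helix - hairpin loop interaction (P2 & L2)	PreQ1
3fu2	A28	G5	C18	2-3	Helix - hairpin loop interaction (P1 & L3)	PreQ1
3dil	A23	G69	A127		Helix - hairpin loop interaction (P2 & L4)	Lysine
3dil	G141	A162	G163		Helix - helix interaction (P1 & P5)	Lysine
3f2q	G12	G93	C30	2-3	Junction - helix - hairpin loop interaction (J1-2, P2, L5)	FMN
2gdi	G19	G42	A47		Helix - junction interaction (P2 & J3-2)	TPP (prokaryotic)
3d2v	A43	A68	U47	2-3	Helix - junction interaction (P4 & J2-4)	TPP (eukaryotic)
3pdr	U24	A106	G100	1-2	Bulged-out residue - helix interaction (P2 & P5)	Magnesium
3pdr	A46	U138	A139		Interaction within junction (J2-6)	Magnesium
3pdr	C35	U34	U150		Bulged-out residue - helix interaction (P2)	Magnesium
3mxh	A95	G14	C93	2-3	Bulged-out residue - helix interaction (P1)	Cyclic di-GMP
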