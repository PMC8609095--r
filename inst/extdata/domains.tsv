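# Structural-domain bounds of the three thyroid autoantigens.
# The Tg acetylcholinesterase-like (ChEL) domain is taken to end at the
# precursor C-terminus (residue 2768).
protein_id	name	start	end
TSHR	signal peptide	1	20
TSHR	LRR9	250	271
TSHR	hinge region	272	413
TSHR	C-peptide	317	366
TSHR	serpentine domain	414	682
TSHR	cytoplasmic tail	683	764
TPO	heme-peroxidase domain	142	738
TPO	CCP/sushi-like domain	740	795
TPO	EGF-like domain	796	846
TPO	transmembrane segment	847	871
TG	acetylcholinesterase-like (ChEL) domain	2188	2768
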