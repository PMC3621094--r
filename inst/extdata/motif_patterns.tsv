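motif_id	gene	anchor	pattern
MHR	gag	300	Q.P..PFQ.Y.DRL
zinc_knuckle_CCHC	gag	420	C..C....H....C
zinc_knuckle_CCHC	gag	450	C..C....H....C
dUTPase	pro	20	AG.DL
dUTPase	pro	60	G.FG.T
dUTPase	pro	95	DR.S
dUTPase	pro	130	.D.DY
dUTPase	pro	165	RG.GGF
protease_DxG	pro	230	D.G
RT_DDD	pol	110	D
RT_DDD	pol	187	D
RT_DDD	pol	188	D
IN_DDE	pol	680	D
IN_DDE	pol	732	D
IN_DDE	pol	768	E
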