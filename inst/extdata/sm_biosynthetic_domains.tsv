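accession	name	category
PF05141	DIT1_PvcA	biosynthetic
PF02668	TauD	biosynthetic
PF00501	AMP-binding	biosynthetic
PF00550	PP-binding	biosynthetic
PF00668	Condensation	biosynthetic
PF00109	ketoacyl-synt	biosynthetic
PF02801	Ketoacyl-synt_C	biosynthetic
PF00698	Acyl_transf_1	biosynthetic
PF01397	Terpene_synth	biosynthetic
PF03936	Terpene_synth_C	biosynthetic
PF19086	Terpene_syn_C_2	biosynthetic
PF00067	p450	biosynthetic
PF01965	DJ-1_PfpI	biosynthetic
PF00106	adh_short	biosynthetic
PF08242	Methyltransf_12	biosynthetic
PF00891	Methyltransf_2	biosynthetic
PF01494	FAD_binding_3	biosynthetic
PF00732	GMC_oxred_N	biosynthetic
PF00561	Abhydrolase_1	biosynthetic
PF07859	Abhydrolase_3	biosynthetic
PF00394	Cu-oxidase	biosynthetic
PF05834	Lycopene_cycl	biosynthetic
PF00583	Acetyltransf_1	biosynthetic
PF01073	3Beta_HSD	biosynthetic
PF00107	ADH_zinc_N	biosynthetic
PF08240	ADH_N	biosynthetic
PF00248	Aldo_ket_red	biosynthetic
PF01593	Amino_oxidase	biosynthetic
PF07690	MFS_1	transport_regulation
PF00083	Sugar_tr	transport_regulation
PF00005	ABC_tran	transport_regulation
PF00664	ABC_membrane	transport_regulation
PF00172	Zn_clus	transport_regulation
PF04082	Fungal_trans	transport_regulation
PF00096	zf-C2H2	transport_regulation
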