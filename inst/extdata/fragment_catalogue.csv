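fragment_code,description
fr_Al_COO,Number of aliphatic carboxylic acids
fr_Al_OH,Number of aliphatic hydroxyl groups
fr_Al_OH_noTert,Number of aliphatic hydroxyl groups excluding tert-OH
fr_ArN,Number of N functional groups attached to aromatics
fr_Ar_COO,Number of Aromatic carboxylic acide
fr_Ar_N,Number of aromatic nitrogens
fr_Ar_NH,Number of aromatic amines
fr_Ar_OH,Number of aromatic hydroxyl groups
fr_COO,Number of carboxylic acids
fr_COO2,Number of carboxylic acids
fr_C_O,Number of carbonyl O
fr_C_O_noCOO,"Number of carbonyl O, excluding COOH"
fr_C_S,Number of thiocarbonyl
fr_HOCCN,Number of C(OH)CCN-Ctert-alkyl or  C(OH)CCNcyclic
fr_Imine,Number of Imines
fr_NH0,Number of Tertiary amines
fr_NH1,Number of Secondary amines
fr_NH2,Number of Primary amines
fr_N_O,Number of hydroxylamine groups
fr_Ndealkylation1,Number of XCCNR groups
fr_Ndealkylation2,"Number of tert-alicyclic amines (no heteroatoms, not quinine-like bridged N)"
fr_Nhpyrrole,Number of H-pyrrole nitrogens
fr_SH,Number of thiol groups
fr_aldehyde,Number of aldehydes
fr_alkyl_carbamate,Number of alkyl carbamates (subject to hydrolysis)
fr_alkyl_halide,Number of alkyl halides
fr_allylic_oxid,Number of allylic oxidation sites excluding steroid dienone
fr_amide,Number of amides
fr_amidine,Number of amidine groups
fr_aniline,Number of anilines
fr_aryl_methyl,Number of aryl methyl sites for hydroxylation
fr_azide,Number of azide groups
fr_azo,Number of azo groups
fr_barbitur,Number of barbiturate groups
fr_benzene,Number of benzene rings
fr_benzodiazepine,Number of benzodiazepines with no additional fused rings
fr_bicyclic,Bicyclic
fr_diazo,Number of diazo groups
fr_dihydropyridine,Number of dihydropyridines
fr_epoxide,Number of epoxide rings
fr_ester,Number of esters
fr_ether,Number of ether oxygens (including phenoxy)
fr_furan,Number of furan rings
fr_guanido,Number of guanidine groups
fr_halogen,Number of halogens
fr_hdrzine,Number of hydrazine groups
fr_hdrzone,Number of hydrazone groups
fr_imidazole,Number of imidazole rings
fr_imide,Number of imide groups
fr_isocyan,Number of isocyanates
fr_isothiocyan,Number of isothiocyanates
fr_ketone,Number of ketones
fr_ketone_Topliss,"Number of ketones excluding diaryl, a,b-unsat. dienones, heteroatom on Calpha"
fr_lactam,Number of beta lactams
fr_lactone,Number of cyclic esters (lactones)
fr_methoxy,Number of methoxy groups -OCH3
fr_morpholine,Number of morpholine rings
fr_nitrile,Number of nitriles
fr_nitro,Number of nitro groups
fr_nitro_arom,Number of nitro benzene ring substituents
fr_nitro_arom_nonortho,Number of non-ortho nitro benzene ring substituents
fr_nitroso,"Number of nitroso groups, excluding NO2"
fr_oxazole,Number of oxazole rings
fr_oxime,Number of oxime groups
fr_para_hydroxylation,Number of para-hydroxylation sites
fr_phenol,Number of phenols
fr_phenol_noOrthoHbond,Number of phenolic OH excluding ortho intramolecular Hbond substituents
fr_phos_acid,Number of phosphoric acid groups
fr_phos_ester,Number of phosphoric ester groups
fr_piperdine,Number of piperdine rings
fr_piperzine,Number of piperzine rings
fr_priamide,Number of primary amides
fr_prisulfonamd,Number of primary sulfonamides
fr_pyridine,Number of pyridine rings
fr_quatN,Number of quaternary nitrogens
fr_sulfide,Number of thioether
fr_sulfonamd,Number of sulfonamides
fr_sulfone,Number of sulfone groups
fr_term_acetylene,Number of terminal acetylenes
fr_tetrazole,Number of tetrazole rings
fr_thiazole,Number of thiazole rings
fr_thiocyan,Number of thiocyanates
fr_thiophene,Number of thiophene rings
fr_unbrch_alkane,Number of unbranched alkanes  of at least 4 members (excludes halogenated alkanes)
fr_urea,Number of urea groups
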