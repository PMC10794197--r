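# Reference counts for the structure-filter oracle test; carbon and
# aromatic-ring counts computed once with an independent cheminformatics
# toolkit (RDKit) on closure-per-ring SMILES writings.
name	smiles	n_carbons	n_aromatic_rings
benzene	c1ccccc1	6	1
toluene	Cc1ccccc1	7	1
ethanol	CCO	2	0
phosgene-like	ClC(Cl)=O	1	0
naphthalene	c1ccc2ccccc2c1	10	2
anthracene	c1ccc2cc3ccccc3cc2c1	14	3
pyridine	c1ccncc1	5	1
pyrrole	c1cc[nH]c1	4	1
furan	c1ccoc1	4	1
thiophene	c1ccsc1	4	1
phenol	Oc1ccccc1	6	1
aniline	Nc1ccccc1	6	1
benzonitrile	N#Cc1ccccc1	7	1
styrene	C=Cc1ccccc1	8	1
biphenyl	c1ccc(-c2ccccc2)cc1	12	2
carbazole	c1ccc2c(c1)[nH]c1ccccc12	12	3
dibenzofuran	c1ccc2c(c1)oc1ccccc12	12	3
dibenzothiophene	c1ccc2c(c1)sc1ccccc12	12	3
fluorene	C1c2ccccc2-c2ccccc21	13	2
triphenylamine	c1ccc(N(c2ccccc2)c2ccccc2)cc1	18	3
triphenyltriazine	c1ccc(-c2nc(-c3ccccc3)nc(-c3ccccc3)n2)cc1	21	4
quinoline	c1ccc2ncccc2c1	9	2
isoquinoline	c1ccc2cnccc2c1	9	2
indole	c1ccc2[nH]ccc2c1	8	2
benzofuran	c1ccc2occc2c1	8	2
pyrene	c1cc2ccc3cccc4ccc(c1)c2c34	16	4
phenanthrene	c1ccc2ccc3ccccc3c2c1	14	3
acridine	c1ccc2nc3ccccc3cc2c1	13	3
phenoxazine	c1ccc2c(c1)Nc1ccccc1O2	12	2
phenothiazine	c1ccc2c(c1)Nc1ccccc1S2	12	2
cyclohexane	C1CCCCC1	6	0
cyclohexanone	O=C1CCCCC1	6	0
adamantane-like	C1CC2CCC1CC2	8	0
acetone	CC(C)=O	3	0
acetic acid	CC(=O)O	2	0
chlorobenzene	Clc1ccccc1	6	1
bromobenzene	Brc1ccccc1	6	1
calcium carbide-ish	CC(C)(C)c1ccccc1	10	1
mesitylene	Cc1cc(C)cc(C)c1	9	1
xylene	Cc1ccccc1C	8	1
nitrobenzene	O=[N+]([O-])c1ccccc1	6	1
benzaldehyde	O=Cc1ccccc1	7	1
benzophenone	O=C(c1ccccc1)c1ccccc1	13	2
diphenylsulfone	O=S(=O)(c1ccccc1)c1ccccc1	12	2
terphenyl	c1ccc(-c2ccc(-c3ccccc3)cc2)cc1	18	3
tetracene	c1ccc2cc3cc4ccccc4cc3cc2c1	18	4
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	8	2
cczpn-like	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)cc1C#N	32	7
4czipn-like	N#Cc1c(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c(C#N)c(-n2c3ccccc3c3ccccc32)c1-n1c2ccccc2c2ccccc21	56	13
spiro-like	C1(c2ccccc2-c2ccccc21)	13	2
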