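# Synthetic name-to-SMILES lookup table for the built-in backend;
# entries for the generator's systematic names are schematic
# (locants not structurally encoded).
name	smiles
benzene	c1ccccc1
toluene	Cc1ccccc1
naphthalene	c1ccc2ccccc2c1
pyridine	c1ccncc1
carbazole	c1ccc2c(c1)[nH]c1ccccc12
triphenylamine	c1ccc(N(c2ccccc2)c2ccccc2)cc1
anthracene	c1ccc2cc3ccccc3cc2c1
chloroform	ClC(Cl)Cl
dichloromethane	ClCCl
nitrogen	N#N
1,2-Bis(carbazol-9-yl)-4,5-dicyanobenzene	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)cc1C#N
1,2-Bis(carbazol-9-yl)-4,5-dicyanopyridine	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)nc1C#N
1,2-Bis(carbazol-9-yl)-4,5-benzonitrile	N#Cc1ccc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c1
2,3-Bis(carbazol-9-yl)-5,6-dicyanobenzene	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)cc1C#N
2,3-Bis(carbazol-9-yl)-5,6-dicyanopyridine	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)nc1C#N
2,3-Bis(carbazol-9-yl)-5,6-benzonitrile	N#Cc1ccc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c1
3,6-Bis(carbazol-9-yl)-1,2-dicyanobenzene	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)cc1C#N
3,6-Bis(carbazol-9-yl)-1,2-dicyanopyridine	N#Cc1cc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)nc1C#N
3,6-Bis(carbazol-9-yl)-1,2-benzonitrile	N#Cc1ccc(-n2c3ccccc3c3ccccc32)c(-n2c3ccccc3c3ccccc32)c1
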