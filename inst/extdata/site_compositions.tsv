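# Ligand composition of the transporter ion-binding-site models
# (LeuT Na1/Na2, Glt_Ph Na1/Na2).
site	residue	fragment
LeuT_Na1	LEU	carboxylate
LeuT_Na1	ALA22	backbone_carbonyl
LeuT_Na1	ASN27	backbone_carbonyl
LeuT_Na1	THR254	backbone_carbonyl
LeuT_Na1	THR254b	hydroxyl
LeuT_Na1	ASN	backbone_carbonyl
LeuT_Na2	GLY20	backbone_carbonyl
LeuT_Na2	VAL23	backbone_carbonyl
LeuT_Na2	ALA351	backbone_carbonyl
LeuT_Na2	THR354	hydroxyl
LeuT_Na2	SER355	hydroxyl
Glt_Na1	GLY306	backbone_carbonyl
Glt_Na1	ASN310	backbone_carbonyl
Glt_Na1	ASN401	backbone_carbonyl
Glt_Na1	ASP405	carboxylate
Glt_Na2	THR308	backbone_carbonyl
Glt_Na2	ILE309	backbone_carbonyl
Glt_Na2	SER349	backbone_carbonyl
Glt_Na2	ILE350	backbone_carbonyl
Glt_Na2	THR352	backbone_carbonyl
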