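# Synthetic idealised starting coordinates (Angstrom) for the transporter-site
# models: ligands of each site placed at chemically sensible ion-oxygen
# distances on packing-optimal directions, NOT extracted from any crystal
# structure. Energy minimisation with each ion defines the working geometry.
site	residue	fragment	atom	x	y	z
LeuT_Na1	LEU	carboxylate	C	 3.0510	 0.0000	 0.0000
LeuT_Na1	LEU	carboxylate	O1	 2.4500	 1.1070	 0.0000
LeuT_Na1	LEU	carboxylate	O2	 2.4500	-1.1070	 0.0000
LeuT_Na1	ALA22	backbone_carbonyl	C	-3.5800	 0.0000	 0.0000
LeuT_Na1	ALA22	backbone_carbonyl	O	-2.3500	 0.0000	 0.0000
LeuT_Na1	ALA22	backbone_carbonyl	H1	-4.1670	-0.9420	 0.0000
LeuT_Na1	ALA22	backbone_carbonyl	H2	-4.1670	 0.9420	 0.0000
LeuT_Na1	ASN27	backbone_carbonyl	C	 0.0000	 3.5800	 0.0000
LeuT_Na1	ASN27	backbone_carbonyl	O	 0.0000	 2.3500	 0.0000
LeuT_Na1	ASN27	backbone_carbonyl	H1	-0.9420	 4.1670	 0.0000
LeuT_Na1	ASN27	backbone_carbonyl	H2	 0.9420	 4.1670	 0.0000
LeuT_Na1	THR254	backbone_carbonyl	C	 0.0000	-3.5800	 0.0000
LeuT_Na1	THR254	backbone_carbonyl	O	 0.0000	-2.3500	 0.0000
LeuT_Na1	THR254	backbone_carbonyl	H1	 0.9420	-4.1670	 0.0000
LeuT_Na1	THR254	backbone_carbonyl	H2	-0.9420	-4.1670	 0.0000
LeuT_Na1	THR254b	hydroxyl	O	 0.0000	 0.0000	 2.4000
LeuT_Na1	THR254b	hydroxyl	H	 0.0000	-0.9230	 2.1360
LeuT_Na1	THR254b	hydroxyl	C	 0.0000	 0.0000	 3.8200
LeuT_Na1	ASN	backbone_carbonyl	C	 0.0000	 0.0000	-3.5800
LeuT_Na1	ASN	backbone_carbonyl	O	 0.0000	 0.0000	-2.3500
LeuT_Na1	ASN	backbone_carbonyl	H1	 0.0000	 0.9420	-4.1670
LeuT_Na1	ASN	backbone_carbonyl	H2	 0.0000	-0.9420	-4.1670
LeuT_Na2	GLY20	backbone_carbonyl	C	 3.0079	-0.9304	-1.7039
LeuT_Na2	GLY20	backbone_carbonyl	O	 1.9744	-0.6108	-1.1185
LeuT_Na2	GLY20	backbone_carbonyl	H1	 3.7794	-0.1831	-1.9833
LeuT_Na2	GLY20	backbone_carbonyl	H2	 3.2227	-1.9829	-1.9833
LeuT_Na2	VAL23	backbone_carbonyl	C	-0.0105	 2.8241	 2.2002
LeuT_Na2	VAL23	backbone_carbonyl	O	-0.0069	 1.8538	 1.4443
LeuT_Na2	VAL23	backbone_carbonyl	H1	-0.9542	 3.2836	 2.5609
LeuT_Na2	VAL23	backbone_carbonyl	H2	 0.9297	 3.2907	 2.5609
LeuT_Na2	ALA351	backbone_carbonyl	C	 0.8918	-2.1288	 2.7367
LeuT_Na2	ALA351	backbone_carbonyl	O	 0.5854	-1.3974	 1.7964
LeuT_Na2	ALA351	backbone_carbonyl	H1	 1.9069	-2.1138	 3.1854
LeuT_Na2	ALA351	backbone_carbonyl	H2	 0.1692	-2.8418	 3.1854
LeuT_Na2	THR354	hydroxyl	O	-2.0094	-1.2695	-0.3327
LeuT_Na2	THR354	hydroxyl	H	-1.2954	-1.9102	-0.2961
LeuT_Na2	THR354	hydroxyl	C	-3.1983	-2.0206	-0.5295
LeuT_Na2	SER355	hydroxyl	O	-0.5979	 1.4271	-1.8346
LeuT_Na2	SER355	hydroxyl	H	-1.3834	 0.9135	-1.6328
LeuT_Na2	SER355	hydroxyl	C	-0.9516	 2.2715	-2.9202
Glt_Na1	GLY306	backbone_carbonyl	C	 2.0669	 2.0669	 2.0669
Glt_Na1	GLY306	backbone_carbonyl	O	 1.3568	 1.3568	 1.3568
Glt_Na1	GLY306	backbone_carbonyl	H1	 1.7397	 3.0719	 2.4058
Glt_Na1	GLY306	backbone_carbonyl	H2	 3.0719	 1.7397	 2.4058
Glt_Na1	ASN310	backbone_carbonyl	C	 2.0669	-2.0669	-2.0669
Glt_Na1	ASN310	backbone_carbonyl	O	 1.3568	-1.3568	-1.3568
Glt_Na1	ASN310	backbone_carbonyl	H1	 3.0719	-1.7397	-2.4058
Glt_Na1	ASN310	backbone_carbonyl	H2	 1.7397	-3.0719	-2.4058
Glt_Na1	ASN401	backbone_carbonyl	C	-2.0669	 2.0669	-2.0669
Glt_Na1	ASN401	backbone_carbonyl	O	-1.3568	 1.3568	-1.3568
Glt_Na1	ASN401	backbone_carbonyl	H1	-3.0719	 1.7397	-2.4058
Glt_Na1	ASN401	backbone_carbonyl	H2	-1.7397	 3.0719	-2.4058
Glt_Na1	ASP405	carboxylate	C	-1.7615	-1.7615	 1.7615
Glt_Na1	ASP405	carboxylate	O1	-0.6317	-2.1973	 1.4145
Glt_Na1	ASP405	carboxylate	O2	-2.1973	-0.6317	 1.4145
Glt_Na2	THR308	backbone_carbonyl	C	 3.0079	-0.9304	-1.7039
Glt_Na2	THR308	backbone_carbonyl	O	 1.9744	-0.6108	-1.1185
Glt_Na2	THR308	backbone_carbonyl	H1	 3.7794	-0.1831	-1.9833
Glt_Na2	THR308	backbone_carbonyl	H2	 3.2227	-1.9829	-1.9833
Glt_Na2	ILE309	backbone_carbonyl	C	-0.0105	 2.8241	 2.2002
Glt_Na2	ILE309	backbone_carbonyl	O	-0.0069	 1.8538	 1.4443
Glt_Na2	ILE309	backbone_carbonyl	H1	-0.9542	 3.2836	 2.5609
Glt_Na2	ILE309	backbone_carbonyl	H2	 0.9297	 3.2907	 2.5609
Glt_Na2	SER349	backbone_carbonyl	C	 0.8918	-2.1288	 2.7367
Glt_Na2	SER349	backbone_carbonyl	O	 0.5854	-1.3974	 1.7964
Glt_Na2	SER349	backbone_carbonyl	H1	 1.9069	-2.1138	 3.1854
Glt_Na2	SER349	backbone_carbonyl	H2	 0.1692	-2.8418	 3.1854
Glt_Na2	ILE350	backbone_carbonyl	C	-2.9974	-1.8937	-0.4963
Glt_Na2	ILE350	backbone_carbonyl	O	-1.9675	-1.2430	-0.3258
Glt_Na2	ILE350	backbone_carbonyl	H1	-2.9857	-3.0005	-0.5776
Glt_Na2	ILE350	backbone_carbonyl	H2	-3.9920	-1.4078	-0.5776
Glt_Na2	THR352	backbone_carbonyl	C	-0.8918	 2.1288	-2.7367
Glt_Na2	THR352	backbone_carbonyl	O	-0.5854	 1.3974	-1.7964
Glt_Na2	THR352	backbone_carbonyl	H1	-1.9069	 2.1138	-3.1854
Glt_Na2	THR352	backbone_carbonyl	H2	-0.1692	 2.8418	-3.1854
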