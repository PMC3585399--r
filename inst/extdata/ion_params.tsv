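# Monovalent cation nonbonded parameters (Joung & Cheatham ion models, TIP3P set).
# rmin2 = Rmin/2 in Angstrom; epsilon in kcal/mol; charge in e; mass in amu.
species	charge	epsilon	rmin2	mass
Li	1	0.0279896	1.025	6.941
Na	1	0.0874393	1.369	22.9898
K	1	0.1936829	1.705	39.0983
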