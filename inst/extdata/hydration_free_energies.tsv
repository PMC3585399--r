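# Hydration free energies (kcal/mol) of the monovalent cations, the single-ion
# scale targeted by the Joung & Cheatham ion models. Used only through pairwise
# differences ddG_hydr(A->B) = dG(B) - dG(A).
species	dG_hydr
Li	-113.5
Na	-87.2
K	-70.5
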