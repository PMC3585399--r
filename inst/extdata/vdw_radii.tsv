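# van der Waals radii (Angstrom, Bondi) used by the occupancy-grid volume tool.
element	radius
H	1.20
C	1.70
N	1.55
O	1.52
Li	1.82
Na	2.27
K	2.75
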