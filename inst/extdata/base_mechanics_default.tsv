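key	value	unit	note
inertia.A	7.61e-44	kg.m2	rotational inertia of adenine about the backbone attachment
inertia.T	4.86e-44	kg.m2	rotational inertia of thymine
inertia.G	8.22e-44	kg.m2	rotational inertia of guanine
inertia.C	4.11e-44	kg.m2	rotational inertia of cytosine
radius.A	5.8e-10	m	distance from the centre of inertia of adenine to the sugar-phosphate chain
radius.T	4.8e-10	m	distance for thymine
radius.G	5.7e-10	m	distance for guanine
radius.C	4.7e-10	m	distance for cytosine
torsion.K	2.27e-18	N.m	backbone torsional constant (uniform default; per-letter torsion.A.. keys override)
dissipation.A	4.25e-34	N.m.s	environmental dissipation coefficient (uniform across letters by default)
dissipation.T	4.25e-34	N.m.s
dissipation.G	4.25e-34	N.m.s
dissipation.C	4.25e-34	N.m.s
bond.AT	0.062	N/m	elastic constant of the protium hydrogen bond, A-T pair
bond.GC	0.096	N/m	elastic constant of the protium hydrogen bond, G-C pair
ecr.AT	2.50e-23	N.m	default critical (break) energy, A-T pair; scans usually override uniformly
ecr.GC	2.50e-23	N.m	default critical (break) energy, G-C pair
kD	1.05	1	deuterium-to-protium bond strength ratio
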