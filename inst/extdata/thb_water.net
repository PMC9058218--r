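# radscav mechanism network v1
[meta]
compound = THB-OH
solvent = water
dielectric = 78.3553
viscosity = 0.000891
temperature = 298.15
pressure = 101325
diffusion_k = 1910000000
pH = 7.4
pKa = .
reference_k_overall = 1940000000
k_overall_ref = 7760000000
seed = .

[forms]
name	net_charge	protons_removed	molar_fraction
THB-OH	0	0	0.797
THB-O-	-1	1	0.2

[pathways]
id	mechanism	composite	composite_id	step	site	form	reaction	delta_rG	delta_G_act	degeneracy	barrierless	imag_freq	reverse_barrier	vertical_energy	k_ref	secondary
hat.n	HAT	.	.	.	1-OH,3-OH,5-OH	THB-OH	hat.n	-124.5	35.5	3	FALSE	.	.	.	36500000	FALSE
raf135.n	RAF	.	.	.	1-C,3-C,5-C	THB-OH	raf135.n	-26.7	54.5	3	FALSE	.	.	.	191000	FALSE
raf246.n	RAF	.	.	.	2-C,4-C,6-C	THB-OH	raf246.n	-34.5	20.5	3	FALSE	.	.	.	71800000	FALSE
setpt.n.1	SET	SET_PT	setpt.n	1	mol	THB-OH	set.thboh	130.5	.	1	FALSE	.	.	.	.	FALSE
setpt.n.2	PT	SET_PT	setpt.n	2	1-OH	THB-OH	pt.thboh.cation	-255	.	1	FALSE	.	.	.	.	FALSE
splet.n.1	SPL	SPLET	splet.n	1	1-OH	THB-OH	spl.thboh	-94.3	.	1	TRUE	.	.	.	.	FALSE
splet.n.2	ET	SPLET	splet.n	2	mol	THB-O-	et.thbo	-30.3	9.2	1	FALSE	.	.	.	7630000000	FALSE
setpt.m.1	SET	SET_PT	setpt.m	1	mol	THB-O-	et.thbo	-30.3	9.2	1	FALSE	.	.	.	7630000000	FALSE
setpt.m.2	PT	SET_PT	setpt.m	2	O	THB-O-	pt.thbodot	-125.7	.	1	TRUE	.	.	.	.	FALSE
splet.m.1	PT	SPLET	splet.m	1	O	THB-O-	pt.thbodot	-125.7	.	1	TRUE	.	.	.	.	FALSE
splet.m.2	ET	SPLET	splet.m	2	mol	THB-O-	et.thbodot	-6.2	0.6	1	FALSE	.	.	.	7940000000	FALSE
hat.s	HAT	.	.	.	3-OH,5-OH	THB-O-	hat.thbodot	-131.8	.	2	TRUE	.	.	.	1910000000	TRUE
raf.s2	RAF	.	.	.	2-C	THB-O-	raf.thbodot.2	-246.7	.	1	TRUE	.	.	.	1910000000	TRUE
raf.s4	RAF	.	.	.	4-C	THB-O-	raf.thbodot.4	-240.7	.	1	TRUE	.	.	.	1910000000	TRUE
raf.s6	RAF	.	.	.	6-C	THB-O-	raf.thbodot.6	-242.4	.	1	TRUE	.	.	.	1910000000	TRUE
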