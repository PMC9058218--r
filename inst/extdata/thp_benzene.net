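# radscav mechanism network v1
[meta]
compound = THP-OH
solvent = benzene
dielectric = 2.2706
viscosity = 0.000604
temperature = 298.15
pressure = 101325
diffusion_k = .
pH = .
pKa = .
reference_k_overall = 131000000
k_overall_ref = 229000000
seed = .

[forms]
name	net_charge	protons_removed	molar_fraction
THP-OH	0	0	1
THP-OH+	1	0	.
THP-O-	-1	1	.

[pathways]
id	mechanism	composite	composite_id	step	site	form	reaction	delta_rG	delta_G_act	degeneracy	barrierless	imag_freq	reverse_barrier	vertical_energy	k_ref	secondary
hat.2	HAT	.	.	.	2-OH	THP-OH	hat.2	-97.7	48.5	1	FALSE	.	.	.	924000	FALSE
hat.4	HAT	.	.	.	4-OH	THP-OH	hat.4	-35.9	42.3	1	FALSE	.	.	.	14500000	FALSE
hat.6	HAT	.	.	.	6-OH	THP-OH	hat.6	-99	45.9	1	FALSE	.	.	.	2560000	FALSE
raf.2	RAF	.	.	.	2-C	THP-OH	raf.2	-32.2	58.2	1	FALSE	.	.	.	14300	FALSE
raf.3	RAF	.	.	.	3-C	THP-OH	raf.3	-27.4	31.5	1	FALSE	.	.	.	99500000	FALSE
raf.4	RAF	.	.	.	4-C	THP-OH	raf.4	2.6	.	1	FALSE	.	.	.	.	FALSE
raf.5	RAF	.	.	.	5-C	THP-OH	raf.5	-32	25.7	1	FALSE	.	.	.	112000000	FALSE
raf.6	RAF	.	.	.	6-C	THP-OH	raf.6	-32.3	58.9	1	FALSE	.	.	.	10600	FALSE
setpt2.1	SET	SET_PT	setpt2	1	mol	THP-OH	set.thpoh	375.5	.	1	FALSE	.	.	.	.	FALSE
setpt2.2	PT	SET_PT	setpt2	2	2-OH	THP-OH+	setpt2.2	-473.6	.	1	FALSE	.	.	.	.	FALSE
setpt4.1	SET	SET_PT	setpt4	1	mol	THP-OH	set.thpoh	375.5	.	1	FALSE	.	.	.	.	FALSE
setpt4.2	PT	SET_PT	setpt4	2	4-OH	THP-OH+	setpt4.2	-392.4	.	1	FALSE	.	.	.	.	FALSE
setpt6.1	SET	SET_PT	setpt6	1	mol	THP-OH	set.thpoh	375.5	.	1	FALSE	.	.	.	.	FALSE
setpt6.2	PT	SET_PT	setpt6	2	6-OH	THP-OH+	setpt6.2	-475	.	1	FALSE	.	.	.	.	FALSE
splet2.1	SPL	SPLET	splet2	1	2-OH	THP-OH	splet2.1	419.6	.	1	FALSE	.	.	.	.	FALSE
splet2.2	ET	SPLET	splet2	2	mol	THP-O-	splet2.2	55.5	.	1	FALSE	.	.	.	.	FALSE
splet4.1	SPL	SPLET	splet4	1	4-OH	THP-OH	splet4.1	402.4	.	1	FALSE	.	.	.	.	FALSE
splet4.2	ET	SPLET	splet4	2	mol	THP-O-	splet4.2	153.9	.	1	FALSE	.	.	.	.	FALSE
splet6.1	SPL	SPLET	splet6	1	6-OH	THP-OH	splet6.1	415.7	.	1	FALSE	.	.	.	.	FALSE
splet6.2	ET	SPLET	splet6	2	mol	THP-O-	splet6.2	58.1	.	1	FALSE	.	.	.	.	FALSE
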