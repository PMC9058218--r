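# radscav mechanism network v1
[meta]
compound = THP-OH
solvent = water
dielectric = 78.3553
viscosity = 0.000891
temperature = 298.15
pressure = 101325
diffusion_k = 1910000000
pH = 7.4
pKa = .
reference_k_overall = 1940000000
k_overall_ref = 5920000000
seed = .

[forms]
name	net_charge	protons_removed	molar_fraction
THP-OH	0	0	0.001
THP-O-	-1	1	0.974
THP-O2-	-2	2	0.025

[pathways]
id	mechanism	composite	composite_id	step	site	form	reaction	delta_rG	delta_G_act	degeneracy	barrierless	imag_freq	reverse_barrier	vertical_energy	k_ref	secondary
hat.26	HAT	.	.	.	2-OH,6-OH	THP-O-	hat.26	-134.6	7.8	2	FALSE	.	.	.	38000000	FALSE
raf.26	RAF	.	.	.	2-C,6-C	THP-O-	raf.26	-32.4	33.4	2	FALSE	.	.	.	29400000	FALSE
raf.35	RAF	.	.	.	3-C,5-C	THP-O-	raf.35	-33.8	.	2	TRUE	.	.	.	1910000000	FALSE
raf.4	RAF	.	.	.	4-C	THP-O-	raf.4	51.6	.	1	FALSE	.	.	.	.	FALSE
setpt.1	SET	SET_PT	setpt	1	mol	THP-O-	set.thpo	87.8	.	1	FALSE	.	.	.	.	FALSE
setpt.2	PT	SET_PT	setpt	2	2-OH	THP-O-	pt.thpodot	-222.4	.	1	FALSE	.	.	.	.	FALSE
splet.1	SPL	SPLET	splet	1	2-OH	THP-O-	spl.thpo	-63.3	.	1	TRUE	.	.	.	1910000000	FALSE
splet.2	ET	SPLET	splet	2	mol	THP-O-	et.thpo2	-71.3	31.3	1	FALSE	.	.	.	20600000	FALSE
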