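# radscav mechanism network v1
[meta]
compound = THB-OH
solvent = benzene
dielectric = 2.2706
viscosity = 0.000604
temperature = 298.15
pressure = 101325
diffusion_k = .
pH = .
pKa = .
reference_k_overall = 131000000
k_overall_ref = 326000000
seed = .

[forms]
name	net_charge	protons_removed	molar_fraction
THB-OH	0	0	1
THB-OH+	1	0	.
THB-O-	-1	1	.

[pathways]
id	mechanism	composite	composite_id	step	site	form	reaction	delta_rG	delta_G_act	degeneracy	barrierless	imag_freq	reverse_barrier	vertical_energy	k_ref	secondary
hat.135	HAT	.	.	.	1-OH,3-OH,5-OH	THB-OH	hat.135	-118.7	34	3	FALSE	.	.	.	36500000	FALSE
raf.135	RAF	.	.	.	1-C,3-C,5-C	THB-OH	raf.135	-28.7	51.7	3	FALSE	.	.	.	191000	FALSE
raf.246	RAF	.	.	.	2-C,4-C,6-C	THB-OH	raf.246	-39	21.5	3	FALSE	.	.	.	71800000	FALSE
setpt.1	SET	SET_PT	setpt	1	mol	THB-OH	setpt.1	357.3	.	1	FALSE	.	.	.	.	FALSE
setpt.2	PT	SET_PT	setpt	2	1-OH	THB-OH+	setpt.2	-476.1	.	1	FALSE	.	.	.	.	FALSE
splet.1	SPL	SPLET	splet	1	1-OH	THB-OH	splet.1	432.4	.	1	FALSE	.	.	.	.	FALSE
splet.2	ET	SPLET	splet	2	mol	THB-O-	splet.2	21.7	.	1	FALSE	.	.	.	.	FALSE
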