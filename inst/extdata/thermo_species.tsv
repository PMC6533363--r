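name	formula	charge	phase	dGf	dHf	S0	source
e-	""	-1	aqueous	0	NA	NA	electron pseudo-species
H+	H	1	aqueous	0	NA	NA	convention
OH-	OH	-1	aqueous	-157.24	NA	NA	CODATA
H2O	H2O	0	liquid	-237.13	NA	NA	CODATA
O2(g)	O2	0	gas	0	NA	NA	reference state
O2(aq)	O2	0	aqueous	16.40	NA	NA	Wagman 1982
O2-	O2	-1	gas	NA	NA	NA	superoxide; reaction-level sums only (see reactions table)
C(s)	C	0	solid	0	NA	NA	graphite reference state
CO2(aq)	CO2	0	aqueous	-385.98	NA	NA	Wagman 1982
HCO3-	HCO3	-1	aqueous	-586.77	NA	NA	Wagman 1982
CO3-2	CO3	-2	aqueous	-527.81	NA	NA	Wagman 1982
CH4(aq)	CH4	0	aqueous	-34.33	NA	NA	Wagman 1982
S(s)	S	0	solid	0	NA	NA	rhombic sulfur reference state
SO4-2	SO4	-2	aqueous	-744.53	NA	NA	Wagman 1982
HSO4-	HSO4	-1	aqueous	-755.91	NA	NA	Wagman 1982
H2S(aq)	H2S	0	aqueous	-27.83	NA	NA	Wagman 1982
HS-	HS	-1	aqueous	12.08	NA	NA	Wagman 1982
S2O3-2	S2O3	-2	aqueous	-522.50	NA	NA	Wagman 1982 (thiosulfate, metastable)
Au(s)	Au	0	solid	0	NA	NA	reference state
Au3+	Au	3	aqueous	440.01	NA	NA	from E0(Au3+/Au) = 1.52 V used in the oxidation chain
Au+	Au	1	aqueous	163.10	NA	NA	from E0(Au+/Au) = 1.69 V
AuOH(aq)	AuOH	0	aqueous	-57.95	NA	NA	Au+ hydrolysis log K1 = -2.8 (Stefansson & Seward-type value)
Au(OH)2-	Au(OH)2	-1	aqueous	-232.31	NA	NA	second hydrolysis log K2 = -11.0
Au(OH)4-	Au(OH)4	-1	aqueous	-481.95	NA	NA	anchored to Au3+ + 4 OH- = Au(OH)4-, log K = 51.35
AuHS(aq)	AuHS	0	aqueous	35.48	NA	NA	Au+ + HS- = AuHS, log beta1 = 24.5 (Renders & Seward-type value)
Au(HS)2-	Au(HS)2	-1	aqueous	15.61	NA	NA	Au+ + 2 HS- = Au(HS)2-, log beta2 = 30.1
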