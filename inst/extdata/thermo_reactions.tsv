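id	equation	logK	n_electrons	E0	source
R1	Au(s) + O2- + 2 H2O = Au(OH)4-	-1.91	0	NA	superoxide oxidation of gold to the tetrahydroxy complex; logK by Hess combination R3 + R4 + 4 R5
R2	Au(s) + 0.75 O2(aq) + 2.5 H2O = Au(OH)4- + H+	-16.09	0	NA	dissolved-oxygen oxidation to the tetrahydroxy complex; logK by Hess combination R6 + R4 + 4 R5
R3	Au(s) + O2- + 4 H+ = Au3+ + 2 H2O	2.74	0	NA	superoxide oxidation of gold; logK from dH = -122.82 kJ/mol, dS = -359.74 J/mol/K at 298 K
R4	Au3+ + 4 OH- = Au(OH)4-	51.35	0	NA	tetrahydroxy complexation in alkaline solution
R5	H2O = H+ + OH-	-14.00	0	NA	water dissociation
R6	Au(s) + 0.75 O2(aq) + 3 H+ = Au3+ + 1.5 H2O	-11.44	0	NA	dissolved-oxygen oxidation of gold
R7	Au(s) = Au3+ + 3 e-	-77.12	3	-1.52	gold oxidation half reaction; E0 stored for the oxidation direction as written
R8	O2- + 4 H+ + 3 e- = 2 H2O	79.84	3	1.57	superoxide/water reduction half reaction; logK from the half-reaction split of R3 against R7
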