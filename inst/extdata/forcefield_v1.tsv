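# grooveDock united-atom parameter table, version 1
# class: atom class label
# r0:    per-atom minimum-energy radius contribution (Angstrom); pair minimum at r0_i + r0_j
# eps:   Lennard-Jones well depth (kcal/mol); pair depth sqrt(eps_i * eps_j)
# sigma: atomic solvation parameter (kcal/mol/A^2), applied to solvent-accessible area
# apolar: 1 if the class enters the hydrophobic contact term
class	r0	eps	sigma	apolar
C3	2.00	0.10	0.016	1
CAR	1.95	0.12	0.016	1
CCO	1.90	0.10	0.016	0
NAM	1.75	0.16	-0.006	0
NPOS	1.75	0.16	-0.050	0
OCO	1.60	0.20	-0.006	0
OOH	1.65	0.20	-0.006	0
ONEG	1.60	0.20	-0.024	0
S	2.00	0.25	0.021	1
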