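atom_name	residue_name	charge_e	rmin_half_A	eps_kcal	solv_param	radius_A
N	ALA	-0.4157	1.824	0.17	0.012	1.55
CA	ALA	0.0337	1.908	0.1094	0.008	1.7
C	ALA	0.5973	1.908	0.086	0.008	1.7
O	ALA	-0.5679	1.6612	0.21	0.017	1.52
CB	ALA	-0.1825	1.908	0.1094	0.008	1.7
N	GLY	-0.4157	1.824	0.17	0.012	1.55
CA	GLY	-0.0252	1.908	0.1094	0.008	1.7
C	GLY	0.5973	1.908	0.086	0.008	1.7
O	GLY	-0.5679	1.6612	0.21	0.017	1.52
C1	BNZ	-0.115	1.908	0.086	0.008	1.7
C2	BNZ	-0.115	1.908	0.086	0.008	1.7
C3	BNZ	-0.115	1.908	0.086	0.008	1.7
C4	BNZ	-0.115	1.908	0.086	0.008	1.7
C5	BNZ	-0.115	1.908	0.086	0.008	1.7
C6	BNZ	-0.115	1.908	0.086	0.008	1.7
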