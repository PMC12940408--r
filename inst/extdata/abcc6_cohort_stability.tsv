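variant	ddg_state1	ddg_state2	ddg_state3	frustration_state1	frustration_state2	frustration_state3	allele_frequency	significance	domain	assigned_function
S317R	0	0.1	-1.4	-1.1	-0.9	-0.9	NA	pathogenic	TMD1	functional_stability
G755R	-0.7	-0.3	-0.1	2.4	3.2	-3.7	3.30e-5	pathogenic	NBD1	atp_binding
G1042S	-0.1	0	8	5.4	2.5	5.2	5.30e-5	vus	TMD2	conformational_dynamics
T1130M	-0.7	-1.4	-1	1.2	1	-0.3	NA	pathogenic	TMD2	functional_stability
R1138Q	1.2	0.5	0.4	1.1	1.1	0.7	5.90e-5	pathogenic	TMD2	functional_stability
G1302R	1.6	3.3	3.6	4	3.9	10.4	3.90e-5	pathogenic	NBD2	atp_binding
R1114C	1	1.4	2	-0.6	1.2	1.8	3.90e-5	pathogenic	TMD2	conformational_dynamics
G1263R	5.6	10.9	6.5	-3.2	-3.4	-7.8	4.00e-5	vus	NBD2	functional_stability
G1296D	0.5	5.1	2.2	-0.8	0	1	5.90e-5	pathogenic	NBD2	functional_stability
R1314W	-0.5	-1.8	5.2	-0.4	-1.3	0.2	6.00e-5	pathogenic	NBD2	functional_stability
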