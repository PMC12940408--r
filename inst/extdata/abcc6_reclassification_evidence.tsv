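variant	allele_frequency	phenotype	predicted_function	in_hotspot	PM1	PP3	PM2	PM5	PP4
R487G	6.57e-6	none	functional_stability	-	Yes	Yes	Yes	Yes	-
R487W	6.57e-6	none	conformational_dynamics	-	Yes	Yes	Yes	Yes	-
K502M	NA	pxe	-	Yes	Yes	-	Yes	Yes	Yes
E521D	NA	pxe	conformational_dynamics	Yes	Yes	Yes	-	Yes	Yes
L522P	NA	both	functional_stability	-	Yes	Yes	-	Yes	Yes
R600L	NA	pxe	conformational_dynamics	-	-	Yes	Yes	Yes	Yes
G663R	NA	none	atp_binding	-	Yes	Yes	Yes	Yes	-
G663S	NA	pxe	functional_stability	-	Yes	Yes	Yes	Yes	Yes
E699G	6.57e-6	both	atp_binding	-	Yes	Yes	-	Yes	Yes
L753P	6.57e-6	pxe	atp_binding	-	Yes	Yes	-	Yes	Yes
S754C	1.97e-6	both	atp_binding	Yes	Yes	Yes	-	Yes	Yes
A766V	NA	none	-	Yes	Yes	-	Yes	Yes	-
R807G	NA	pxe	functional_stability	-	-	Yes	Yes	Yes	Yes
V810M	3.29e-6	both	functional_stability	-	Yes	Yes	-	Yes	Yes
T811A	NA	none	functional_stability	-	Yes	Yes	Yes	Yes	-
L1063P	NA	pxe	functional_stability	-	-	Yes	Yes	Yes	Yes
R1235G	6.58e-6	none	-	Yes	Yes	-	Yes	Yes	-
G1299R	NA	none	atp_binding	Yes	Yes	Yes	Yes	Yes	-
A1303T	6.57e-6	none	atp_binding	-	Yes	Yes	Yes	Yes	-
G1311E	NA	pxe	regulation	Yes	Yes	Yes	-	Yes	Yes
A1318T	NA	gaci	-	Yes	Yes	-	Yes	Yes	Yes
R1339S	6.58e-6	none	functional_stability	Yes	Yes	Yes	Yes	Yes	-
R1339L	NA	pxe	-	Yes	Yes	-	Yes	Yes	Yes
P1346S	6.57e-6	pxe	functional_stability	-	Yes	Yes	-	Yes	Yes
V1404M	5.91e-6	both	atp_binding	-	Yes	Yes	-	Yes	Yes
Q1406H	6.57e-6	none	-	-	Yes	-	Yes	Yes	-
I1424T	NA	pxe	functional_stability	-	Yes	Yes	-	Yes	Yes
R1459C	1.31e-6	both	atp_binding	-	Yes	Yes	-	Yes	Yes
G1481S	3.94e-6	both	functional_stability	-	Yes	Yes	-	Yes	Yes
P1483Q	1.31e-6	both	regulation	-	Yes	Yes	-	Yes	Yes
P1483L	5.26e-6	both	regulation	-	Yes	Yes	-	Yes	Yes
F1493L	5.92e-6	both	functional_stability	-	Yes	Yes	-	Yes	Yes
G1501C	1.31e-6	none	functional_stability	-	Yes	Yes	Yes	Yes	-
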