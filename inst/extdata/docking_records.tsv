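receptor	ligand	delta_g	ki_reported
AKT1	Kaempferol	-7.04	6.88
AKT1	Quercetin	-7.23	4.97
PIK3R1	Quercetin	-6.12	32.84
ESR1	Myricanone	-8.16	1.04
MYC	Quercetin	-5.96	42.99
NR3C1	Wallichilide	-10.44	0.02
IL1B	Quercetin	-8.28	0.84
TP53	Quercetin	-6.67	12.95
ERBB2	Quercetin	-5.12	175.26
CAV1	Quercetin	-5.5	92.39
AR	Kaempferol	-8.26	0.88
IGF2	Quercetin	-5.15	167.49
ALB	Beta-Carotene	-12.61	0.00057
CTNNB1	Beta-Carotene	-8.43	0.66
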