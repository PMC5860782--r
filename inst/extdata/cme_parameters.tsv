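parameter	description	value	units
Vol_CP	Cytosol volume	37.2	um^3
SA_PM	Plasma membrane surface area	75.7	um^2
sigma	KD 3D-to-2D conversion lengthscale	1	nm
Kd_CHC_CHC	Clathrin heavy chain polymerization	100	uM
Kd_CHC_ENT	Clathrin heavy chain binding to ENT1/2	22	uM
Kd_CHC_YAP	Clathrin heavy chain binding to YAP1801/2	160	uM
Kd_EDE_ENT	EDE1 to ENT1/2 binding	12	uM
Kd_EDE_YAP	EDE1 to YAP1802 binding	0.6	uM
Kd_EDE_EDE	EDE1 dimerization	0.127	uM
Kd_CHC_CLC	Clathrin heavy chain to light chain binding	1e-04	uM
Kd_CLC_SLA	Clathrin light chain to SLA2 binding	22	uM
Kd_SLA_SLA	SLA2 dimerization	0.001	uM
Kd_SYP_SYP	SYP1 dimerization	2.5	uM
Kd_SYP_EDE	SYP1 to EDE1 binding	0.227	uM
Kd_L_ENT	ENT1/2 binding to lipid	0.02	uM
Kd_L_YAP	YAP1801 binding to lipid	0.3	uM
Kd_L_SLA	SLA2 binding to lipid	0.2	uM
Kd_L_SYP	SYP1 binding to lipid	53	uM
k_off	Dissociation rate for all bonds	1	s^-1
L_0	Density of membrane recruiter lipids	25292	lipids/um^2
CHC1_0	Total clathrin heavy chain trimers	6426	copies
CLC1_0	Total clathrin light chains	14538	copies
EDE1_0	EDE1 total proteins	5964	copies
ENT_0	ENT1/2 total proteins	3075	copies
YAP1801_0	YAP1801 total proteins	357	copies
YAP1802_0	YAP1802 total proteins	264	copies
SLA2_0	SLA2 total proteins	3904	copies
SYP1_0	SYP1 total proteins	2467	copies
T_vesicle	Full triskelia in a completed vesicle	100	count
k_dump	Deletion rate for completed vesicles	1000	s^-1
k_recyc	Protein recycling rate to the cytoplasm	1000	s^-1
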