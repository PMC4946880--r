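# Default parameter table for the SHR/SCR compartment model (per-hour rates,
# arbitrary concentration units).  Provenance:
#   measured   - scanning-FCS measurement (RICS diffusion coefficients) or
#                direct image measurement (cell areas)
#   constraint - fixed by a qualitative constraint (logistic switch shape,
#                SCR threshold at 60% of steady state)
#   estimated  - tuned against the N&B/cross-N&B composition data via
#                estimate_parameters(); see the methods vignette
parameter	value	provenance	description
k1	10	estimated	SHR production rate in the vasculature
D1	2.45	measured	SHR diffusion coefficient, vasculature+endodermis (um^2/s)
A1	100	measured	mean vascular cell area (um^2)
D2	2.40	measured	SHR diffusion coefficient in SCR knockdown (um^2/s)
A2	150	measured	mean endodermal cell area (um^2)
d1	0.1	estimated	degradation of vascular SHR
d2	10	estimated	degradation of endodermal SHR monomer (calibrated upward)
d3	1	estimated	degradation of SHR homodimer
L	0.5	constraint	maximum homodimerisation rate
k	0.1	constraint	logistic steepness of k2(C)
C0	360	constraint	SCR threshold (60% of SCR steady state)
k3	162	estimated	maximum SCR production rate
K1D	100	estimated	first Hill dissociation constant
K2D	50	estimated	second Hill dissociation constant (calibrated downward)
d4	0.25	estimated	SCR degradation
k4	0.01	estimated	1:1 complex association rate
d5	0.5	estimated	1:1 complex degradation
k5	0.0221	estimated	2:1 complex association rate
d6	0.5	estimated	2:1 complex degradation
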