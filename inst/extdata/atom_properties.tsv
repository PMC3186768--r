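# pgpsub atomic property table, version 1
# mass: IUPAC 2021 standard atomic weights (u)
# sanderson_en: Sanderson electronegativity (dimensionless), Sanderson (1983)
# polarizability: static dipole polarizability (A^3), CRC Handbook 95th ed.
# vdw_volume: van der Waals volume (A^3) from Bondi radii, Zhao et al. (2003)
# Descriptor weights are these values divided by the carbon value.
element	mass	sanderson_en	polarizability	vdw_volume
H	1.008	2.592	0.667	7.24
C	12.011	2.746	1.760	20.58
N	14.007	3.194	1.100	15.60
O	15.999	3.654	0.802	14.71
F	18.998	4.000	0.557	13.31
P	30.974	2.515	3.630	24.43
S	32.060	2.957	2.900	24.43
Cl	35.450	3.475	2.180	22.45
Br	79.904	3.219	3.050	26.52
I	126.904	2.778	5.350	32.52
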