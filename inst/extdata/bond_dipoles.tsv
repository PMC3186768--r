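# pgpsub bond dipole moment table, version 1
# Bond dipole moments in debye for heavy-atom bond types, from standard group
# moment compilations (Smyth 1955; CRC Handbook). Lookup is symmetric in the
# element pair; homonuclear bonds of any order have dipole 0 and are omitted.
# order: single, double, triple, aromatic. Missing (pair, order) combinations
# fall back to the single-bond entry for the pair, else 0.
element_a	element_b	order	dipole
C	N	single	0.22
C	N	double	1.40
C	N	triple	3.50
C	N	aromatic	0.80
C	O	single	0.74
C	O	double	2.30
C	O	aromatic	1.50
C	S	single	0.90
C	S	double	2.00
C	S	aromatic	1.45
C	F	single	1.41
C	Cl	single	1.46
C	Br	single	1.38
C	I	single	1.19
C	P	single	0.50
N	O	single	0.30
N	O	double	2.00
S	O	single	0.60
S	O	double	2.80
P	O	single	1.00
P	O	double	2.70
N	S	single	0.50
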