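atom_class	epsilon	rmin_half	default_charge
H	0.046	0.2245	0.09
C	0.070	1.9924	0.00
N	0.200	1.8500	-0.47
O	0.120	1.7000	-0.51
S	0.450	2.0000	-0.09
P	0.585	2.1500	1.50
F	0.097	1.6300	-0.22
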