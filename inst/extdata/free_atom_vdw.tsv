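# Free-atom van der Waals reference data (Hartree atomic units).
# alpha0: static dipole polarizability (Bohr^3)
# c6:     homoatomic C6 dispersion coefficient (Ha Bohr^6)
# rvdw:   van der Waals radius (Bohr)
# Values from the standard high-accuracy free-atom reference set used by
# Hirshfeld-volume-scaled dispersion models.
element	alpha0	c6	rvdw
H	4.500	6.500	3.100
B	21.000	99.500	4.170
C	12.000	46.600	3.590
N	7.400	24.200	3.340
O	5.400	15.600	3.190
F	3.800	9.500	3.040
Si	37.000	305.000	4.200
P	25.000	185.000	4.200
S	19.600	134.000	3.860
Cl	15.000	94.600	3.710
Br	20.000	162.000	3.930
I	35.000	385.000	4.170
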