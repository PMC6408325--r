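# Van der Waals radii (Angstrom) assigned to heavy atoms for SASA and clash
# detection. Fixed bundled table so surface areas are reproducible across runs.
element	radius
C	1.70
N	1.55
O	1.52
S	1.80
P	1.80
H	1.20
SE	1.90
F	1.47
CL	1.75
BR	1.85
I	1.98
MG	1.73
ZN	1.39
CA	2.31
NA	2.27
K	2.75
FE	1.94
MN	1.93
X	1.70
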