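# Tubulin secondary-structure-element registry, canonical alpha-tubulin numbering.
# Domain partition and named elements used by the bend-angle, helix-shift and
# contact-attribution stages. Users may substitute their own definitions by
# passing a file of the same layout to loadSseRegistry().
# category: helix | strand | loop | domain
name	category	start	end
n_terminal	domain	1	205
intermediate	domain	206	381
c_terminal	domain	382	440
S1	strand	3	9
H1	helix	10	28
H1-S2	loop	38	46
S2	strand	63	68
H2	helix	74	88
S3	strand	93	98
H3	helix	107	126
S4	strand	133	138
H4	helix	144	158
S5	strand	163	169
H5	helix	177	191
S6	strand	198	202
H6	helix	206	216
H7	helix	224	243
T7	loop	244	251
H8	helix	252	260
S7	strand	265	270
H9	helix	283	292
S8	strand	312	316
S8-H10	loop	317	319
H10	helix	320	330
H10-S9	loop	331	349
S9	strand	350	356
S10	strand	361	366
H11	helix	383	395
H12	helix	418	432
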