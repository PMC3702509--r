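fragment	heavy_atoms	kd_uM	le_published	nmr_confirmed
A	13	18.3	0.50	TRUE
B	16	68.2	0.35	FALSE
C	17	110	0.32	TRUE
D	17	50.3	0.34	TRUE
E	18	67	0.32	TRUE
F	18	128	0.29	TRUE
G	19	50	0.31	FALSE
H	19	111	0.28	TRUE
I	19	220	0.26	TRUE
J	20	120	0.27	TRUE
K	21	53.4	0.28	TRUE
L	23	70	0.25	TRUE
M	25	55	0.23	TRUE
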