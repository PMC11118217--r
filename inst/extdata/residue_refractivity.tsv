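residue	dndc_mL_per_g	mass_g_per_mol	source
A	0.167	71.08	mcmeekin1964
R	0.206	156.19	mcmeekin1964
N	0.192	114.10	mcmeekin1964
D	0.197	115.09	mcmeekin1964
C	0.206	103.14	mcmeekin1964
Q	0.186	128.13	mcmeekin1964
E	0.183	129.12	mcmeekin1964
G	0.175	57.05	mcmeekin1964
H	0.219	137.14	mcmeekin1964
I	0.179	113.16	mcmeekin1964
L	0.173	113.16	mcmeekin1964
K	0.181	128.17	mcmeekin1964
M	0.204	131.19	mcmeekin1964
F	0.244	147.18	mcmeekin1964
P	0.165	97.12	mcmeekin1964
S	0.170	87.08	mcmeekin1964
T	0.172	101.10	mcmeekin1964
W	0.277	186.21	mcmeekin1964
Y	0.240	163.18	mcmeekin1964
V	0.172	99.13	mcmeekin1964
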