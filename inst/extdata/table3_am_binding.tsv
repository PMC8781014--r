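site	E_VDW	E_eel	G_pol	G_nonpol	TS	G_total
B	-27.47 ± 0.49	2.42 ± 0.18	7.11 ± 0.31	-2.65 ± 0.03	-17.80 ± 0.09	-2.79 ± 0.64
G	-28.83 ± 0.22	-3.92 ± 0.21	12.03 ± 0.43	-2.30 ± 0.02	-17.36 ± 0.15	-5.66 ± 0.68
H	-56.18 ± 0.08	-24.69 ± 0.50	24.41 ± 0.19	-3.79 ± 0.01	-26.13 ± 0.08	-34.12 ± 0.43
I	-32.57 ± 0.08	-3.01 ± 0.06	10.97 ± 0.08	-2.58 ± 0.02	-18.47 ± 0.07	-8.73 ± 0.12
J	-25.14 ± 0.41	-9.96 ± 0.73	23.44 ± 0.55	-2.15 ± 0.03	-17.38 ± 0.17	3.57 ± 0.44
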