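site	E_VDW	E_eel	G_pol	G_nonpol	TS	G_total
No Ligand	-53.69 ± 0.21	-18.76 ± 0.18	24.97 ± 0.27	-4.88 ± 0.01	-24.96 ± 0.07	-27.39 ± 0.23
B	-56.87 ± 0.21	-20.24 ± 0.65	25.14 ± 0.27	-4.96 ± 0.00	-25.47 ± 0.02	-31.47 ± 0.18
G	-58.05 ± 0.25	-9.74 ± 0.36	23.54 ± 0.19	-4.96 ± 0.01	-25.56 ± 0.09	-23.66 ± 0.50
H	-56.21 ± 0.27	-11.57 ± 0.40	21.30 ± 0.15	-4.91 ± 0.01	-25.31 ± 0.04	-26.09 ± 0.01
H*	-60.94 ± 0.34	-12.78 ± 0.38	20.00 ± 0.19	-4.88 ± 0.02	-26.55 ± 0.05	-32.04 ± 0.29
I	-57.95 ± 0.21	-18.73 ± 0.23	23.42 ± 0.11	-4.77 ± 0.01	-26.20 ± 0.03	-31.83 ± 0.15
J	-57.69 ± 0.13	-26.88 ± 0.50	24.26 ± 0.16	-4.80 ± 0.01	-26.81 ± 0.06	-38.29 ± 0.40
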