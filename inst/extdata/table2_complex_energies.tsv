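site	E_VDW	E_eel	E_int	G_pol	G_nonpol	TS	G_total
B	-1213.52 ± 1.02	-6211.37 ± 5.31	7207.92 ± 5.38	-3699.43 ± 2.93	87.94 ± 0.14	3406.36 ± 0.68	-7234.83 ± 8.24
G	-1231.75 ± 0.80	-6271.31 ± 10.20	7216.25 ± 6.29	-3646.51 ± 16.49	89.27 ± 0.10	3407.79 ± 0.35	-7251.85 ± 1.51
H	-1249.43 ± 3.56	-6356.62 ± 3.06	7216.04 ± 2.52	-3623.11 ± 3.62	85.70 ± 0.01	3393.90 ± 0.08	-7321.31 ± 7.11
I	-1257.82 ± 1.33	-6363.47 ± 9.32	7204.73 ± 4.78	-3520.82 ± 6.20	86.77 ± 0.07	3395.35 ± 0.13	-7245.96 ± 11.47
J	-1224.81 ± 1.81	-6261.38 ± 3.18	7224.34 ± 5.16	-3738.61 ± 7.43	87.58 ± 0.04	3401.05 ± 0.31	-7313.93 ± 4.07
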