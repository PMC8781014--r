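AM	B	C	G	H	I	J	K
C-2	-7.26	N/A	-6.68	-7.20	-7.31	-5.64	-6.95
TBC	-6.04	-4.44	-5.42	-2.79	-6.39	-4.35	-5.75
CBD	-6.28	-4.74	-5.89	-4.21	-5.92	-4.13	-5.78
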