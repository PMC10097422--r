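pair	k_fret	R	kappa_sq	chl_a_pair
b605_Q -> a305_L	0.27	13.53	1.00	No
b605_W -> a2004_O	0.29	13.98	1.28	No
b608_Q -> a224_H	0.19	16.56	2.38	No
a612_W -> a201_K	0.29	16.24	0.95	Yes
a614_R -> b606_Lhca6	0.02	17.39	0.35	No
b605_T -> a2003_O	0.05	16.84	0.66	No
a610_W -> a201_K	0.00	18.46	0.01	Yes
Mdp609_Q -> a224_H	0.01	19.08	1.36	No
b606_Q -> a224_H	0.03	19.28	0.80	No
b617_T -> a2004_O	0.05	19.40	1.63	No
a612_R -> b606_Lhca6	0.00	18.87	0.70	No
b617_W -> a203_K	0.06	19.75	2.02	No
b617_W -> a204_K	0.05	20.00	1.83	No
a612_R -> a610_Lhca6	0.15	19.37	1.42	Yes
b605_T -> a2001_O	0.02	19.67	0.71	No
a611_R -> a302_H	0.17	20.08	1.99	Yes
b605_Q -> a2005_O	0.03	21.20	1.51	No
b617_R -> a604_Lhca6	0.02	20.83	0.87	No
a611_R -> a609_Lhca6	0.05	20.79	0.70	Yes
b617_W -> a206_K	0.02	20.86	0.79	No
b605_Q -> a224_H	0.01	21.37	0.79	No
b617_W -> a2004_O	0.00	21.54	0.01	No
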