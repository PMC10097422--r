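code	species	family
CLA	chl_a	chlorophyll
CHL	chl_b	chlorophyll
DVP	mdp	chlorophyll
BCR	car_bcr	carotenoid
XAT	car_xat	carotenoid
NEX	car_nex	carotenoid
NEN	car_nex	carotenoid
LUT	car_lut	carotenoid
PRX	car_prx	carotenoid
DLT	car_dlt	carotenoid
PQN	quinone	other
SF4	fe4s4	other
LHG	lipid	other
LMG	lipid	other
DGD	lipid	other
SQD	lipid	other
HOH	water	other
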