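chain	complex
A	PSI core
B	PSI core
C	PSI core
D	PSI core
E	PSI core
F	PSI core
G	PSI core
H	PSI core
I	PSI core
J	PSI core
K	PSI core
L	PSI core
M	PSI core
N	PSI core
O	PSI core
S	Trimer 1
T	Trimer 1
U	Trimer 1
P	Trimer 2
Q	Trimer 2
R	Trimer 2
V	Trimer 3
W	Trimer 3
X	Trimer 3
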