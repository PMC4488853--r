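subpop	haplogroup	count
AL	U	12
TU	U	12
HA	U	12
VA	U	12
UU	U	11
LMO	U	11
AL	V	2
TU	V	2
HA	V	2
VA	V	2
UU	V	2
LMO	V	2
AL	H	23
TU	H	22
HA	H	22
VA	H	22
UU	H	22
LMO	H	22
AL	J	6
TU	J	6
HA	J	6
VA	J	5
UU	J	5
LMO	J	5
AL	T	5
TU	T	5
HA	T	5
VA	T	5
UU	T	4
LMO	T	4
AL	K	4
TU	K	4
HA	K	4
VA	K	4
UU	K	4
LMO	K	4
AL	HV	4
TU	HV	4
HA	HV	3
VA	HV	3
UU	HV	3
LMO	HV	3
AL	I	3
TU	I	3
HA	I	3
VA	I	3
UU	I	3
LMO	I	3
AL	W	3
TU	W	3
HA	W	2
VA	W	2
UU	W	2
LMO	W	2
AL	X	2
TU	X	2
HA	X	2
VA	X	2
UU	X	2
LMO	X	1
AL	D	2
TU	D	2
HA	D	1
VA	D	1
UU	D	1
LMO	D	1
AL	N	2
TU	N	1
HA	N	1
VA	N	1
UU	N	1
LMO	N	1
AL	R	1
TU	R	1
HA	R	1
VA	R	1
UU	R	1
LMO	R	1
AL	Z	1
TU	Z	1
HA	Z	1
VA	Z	1
UU	Z	1
MI	U	19
CF	U	19
KU	U	19
KY	U	19
NC	U	19
OU	U	19
LA	U	18
MI	V	3
CF	V	3
KU	V	3
KY	V	3
NC	V	2
OU	V	2
LA	V	2
MI	H	21
CF	H	21
KU	H	21
KY	H	20
NC	H	20
OU	H	20
LA	H	20
MI	J	2
CF	J	2
KU	J	2
KY	J	2
NC	J	2
OU	J	2
LA	J	1
MI	T	4
CF	T	4
KU	T	3
KY	T	3
NC	T	3
OU	T	3
LA	T	3
MI	K	4
CF	K	3
KU	K	3
KY	K	3
NC	K	3
OU	K	3
LA	K	3
MI	HV	3
CF	HV	3
KU	HV	3
KY	HV	3
NC	HV	3
OU	HV	3
LA	HV	3
MI	I	3
CF	I	3
KU	I	3
KY	I	3
NC	I	3
OU	I	2
LA	I	2
MI	W	3
CF	W	2
KU	W	2
KY	W	2
NC	W	2
OU	W	2
LA	W	2
MI	X	2
CF	X	2
KU	X	2
KY	X	2
NC	X	1
OU	X	1
LA	X	1
MI	D	2
CF	D	2
KU	D	1
KY	D	1
NC	D	1
OU	D	1
LA	D	1
MI	N	1
CF	N	1
KU	N	1
KY	N	1
NC	N	1
OU	N	1
LA	N	1
MI	R	1
CF	R	1
KU	R	1
KY	R	1
NC	R	1
OU	R	1
MI	Z	1
CF	Z	1
KU	Z	1
KY	Z	1
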