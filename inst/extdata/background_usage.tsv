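codon	aa	rel
AAA	K	0.5
AAC	N	0.5
AAG	K	0.5
AAT	N	0.5
ACA	T	0.25
ACC	T	0.25
ACG	T	0.25
ACT	T	0.25
AGA	R	0.166666666666667
AGC	S	0.166666666666667
AGG	R	0.166666666666667
AGT	S	0.166666666666667
ATA	I	0.333333333333333
ATC	I	0.333333333333333
ATG	M	1
ATT	I	0.333333333333333
CAA	Q	0.5
CAC	H	0.5
CAG	Q	0.5
CAT	H	0.5
CCA	P	0.25
CCC	P	0.25
CCG	P	0.25
CCT	P	0.25
CGA	R	0.166666666666667
CGC	R	0.166666666666667
CGG	R	0.166666666666667
CGT	R	0.166666666666667
CTA	L	0.166666666666667
CTC	L	0.166666666666667
CTG	L	0.166666666666667
CTT	L	0.166666666666667
GAA	E	0.5
GAC	D	0.5
GAG	E	0.5
GAT	D	0.5
GCA	A	0.21
GCC	A	0.27
GCG	A	0.36
GCT	A	0.16
GGA	G	0.25
GGC	G	0.25
GGG	G	0.25
GGT	G	0.25
GTA	V	0.25
GTC	V	0.25
GTG	V	0.25
GTT	V	0.25
TAA	*	0.333333333333333
TAC	Y	0.5
TAG	*	0.333333333333333
TAT	Y	0.5
TCA	S	0.166666666666667
TCC	S	0.166666666666667
TCG	S	0.166666666666667
TCT	S	0.166666666666667
TGA	*	0.333333333333333
TGC	C	0.5
TGG	W	1
TGT	C	0.5
TTA	L	0.166666666666667
TTC	F	0.5
TTG	L	0.166666666666667
TTT	F	0.5
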