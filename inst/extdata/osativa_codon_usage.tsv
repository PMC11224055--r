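codon	aa	per1000
TTT	F	20.0
TTC	F	24.3
TTA	L	8.8
TTG	L	18.4
CTT	L	19.8
CTC	L	27.0
CTA	L	9.7
CTG	L	18.0
ATT	I	18.8
ATC	I	21.8
ATA	I	11.0
ATG	M	24.4
GTT	V	19.4
GTC	V	17.5
GTA	V	7.7
GTG	V	24.8
TCT	S	14.6
TCC	S	14.6
TCA	S	13.3
TCG	S	9.3
AGT	S	11.0
AGC	S	14.7
CCT	P	14.7
CCC	P	9.2
CCA	P	16.0
CCG	P	12.4
ACT	T	12.7
ACC	T	14.2
ACA	T	13.4
ACG	T	8.7
GCT	A	22.6
GCC	A	24.0
GCA	A	17.2
GCG	A	15.2
TAT	Y	10.6
TAC	Y	15.3
TAA	*	1.0
TAG	*	0.8
TGA	*	1.5
CAT	H	13.0
CAC	H	13.5
CAA	Q	15.1
CAG	Q	18.9
AAT	N	15.6
AAC	N	19.4
AAA	K	16.7
AAG	K	31.2
GAT	D	26.5
GAC	D	20.9
GAA	E	22.0
GAG	E	34.2
TGT	C	8.5
TGC	C	12.4
TGG	W	13.0
CGT	R	6.6
CGC	R	12.1
CGA	R	4.7
CGG	R	10.4
AGA	R	9.8
AGG	R	14.3
GGT	G	15.7
GGC	G	25.0
GGA	G	16.9
GGG	G	11.6
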