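aa	C	H	N	O	S	labile	methyl	volume
G	2	3	1	1	0	1	0	60.1
A	3	5	1	1	0	1	3	88.6
S	3	5	1	2	0	2	0	89.0
P	5	7	1	1	0	0	0	112.7
V	5	9	1	1	0	1	6	140.0
T	4	7	1	2	0	2	3	116.1
C	3	5	1	1	1	2	0	108.5
L	6	11	1	1	0	1	6	166.7
I	6	11	1	1	0	1	6	166.7
N	4	6	2	2	0	3	0	114.1
D	4	5	1	3	0	2	0	111.1
Q	5	8	2	2	0	3	0	143.8
K	6	12	2	1	0	3	0	168.6
E	5	7	1	3	0	2	0	138.4
M	5	9	1	1	1	1	3	162.9
H	6	7	3	1	0	2	0	153.2
F	9	9	1	1	0	1	0	189.9
R	6	12	4	1	0	5	0	173.4
Y	9	9	1	2	0	2	0	193.6
W	11	10	2	1	0	2	0	227.8
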