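# SYNTHETIC placeholder diagnostic-site table. The real residue positions
# distinguishing the two laboratory-mouse deaminase alleles are published
# only in figure form, not machine-readably; this file exists so that the
# haplotype engine ships runnable. Replace with a curated table for any
# real analysis.
column	residueA	residueB
34	G	E
37	K	R
38	G	D
60	S	T
75	Q	H
102	V	I
134	V	A
135	Q	L
136	D	N
160	R	K
184	T	M
200	M	V
201	D	G
202	P	S
225	R	Q
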