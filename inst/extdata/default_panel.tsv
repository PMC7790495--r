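position	wt	mutants	codon
103	E	K	
118	T	S	
161	D	G	
162	H	Q	
173	S	R	
219	K	R	
220	Y	N	
299	D	E	
315	V	A	
319	G	D,E	GRM
320	G	D,N,S	RRT
321	A	G	
329	A	T	
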