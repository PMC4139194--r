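# Nearest-neighbour free-energy parameters for RNA/RNA Watson-Crick
# helices at 37 C, kcal/mol (Xia et al. 1998 / Turner 2004 set).
# 'stack' keys give the top-strand dinucleotide 5'->3'; the bottom strand
# is its Watson-Crick complement. Dangling-end terms are not included.
# parameter_set: xia1998-wc-v1
type	key	dg
init	-	4.09
symmetry	-	0.43
terminal_au	-	0.45
stack	AA	-0.93
stack	UU	-0.93
stack	AU	-1.10
stack	UA	-1.33
stack	CU	-2.08
stack	AG	-2.08
stack	CA	-2.11
stack	UG	-2.11
stack	GU	-2.24
stack	AC	-2.24
stack	GA	-2.35
stack	UC	-2.35
stack	CG	-2.36
stack	GG	-3.26
stack	CC	-3.26
stack	GC	-3.42
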