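taxon_id	name	rank	parent_id
1	root	no rank	1
2	Bacteria	superkingdom	1
1224	Proteobacteria	phylum	2
1236	Gammaproteobacteria	class	1224
91347	Enterobacterales	order	1236
543	Enterobacteriaceae	family	91347
561	Escherichia	genus	543
562	Escherichia coli	species	561
590	Salmonella	genus	543
28901	Salmonella enterica	species	590
1239	Firmicutes	phylum	2
91061	Bacilli	class	1239
186826	Lactobacillales	order	91061
1300	Streptococcaceae	family	186826
1301	Streptococcus	genus	1300
1313	Streptococcus pneumoniae	species	1301
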