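mirna_id	target_id	target_class	provenance
hsa-miR-455-3p	ZNF117	mRNA	published_pathway
hsa-miR-455-3p	OTUD4	mRNA	published_pathway
hsa-miR-455-5p	ZNF117	mRNA	published_pathway
hsa-miR-3609	RRN3	mRNA	published_pathway
hsa-miR-32-5p	RRN3	mRNA	published_pathway
hsa-miR-31-5p	OTUD4	mRNA	published_pathway
hsa-miR-142-5p	OTUD4	mRNA	synthetic
hsa-miR-218-5p	RRN3	mRNA	synthetic
hsa-miR-455-3p	XIST	lncRNA	published_pathway
hsa-miR-455-3p	KCNQ1OT1	lncRNA	published_pathway
hsa-miR-455-5p	OIP5-AS1	lncRNA	published_pathway
hsa-miR-455-5p	KCNQ1OT1	lncRNA	published_pathway
hsa-miR-3609	KCNQ1OT1	lncRNA	published_pathway
hsa-miR-32-5p	XIST	lncRNA	published_pathway
hsa-miR-32-5p	OIP5-AS1	lncRNA	published_pathway
hsa-miR-32-5p	KCNQ1OT1	lncRNA	published_pathway
hsa-miR-31-5p	XIST	lncRNA	published_pathway
hsa-miR-31-5p	KCNQ1OT1	lncRNA	published_pathway
hsa-miR-142-5p	NEAT1	lncRNA	synthetic
hsa-miR-218-5p	ZNF561-AS1	lncRNA	synthetic
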