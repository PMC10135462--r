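node_id	direction
OTUD4	up
RRN3	up
ZNF117	up
hsa-miR-142-5p	down
hsa-miR-455-3p	down
hsa-miR-32-5p	down
hsa-miR-31-5p	down
hsa-miR-455-5p	down
hsa-miR-218-5p	down
hsa-miR-3609	down
KCNQ1OT1	up
NEAT1	ns
XIST	up
OIP5-AS1	up
ZNF561-AS1	down
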