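# Published per-marker validation counts for the cassava Bemisia tabaci
# KASP panel. Each reference class groups the samples sharing an expected
# call at that marker; `class` is the reference-method (NextRAD-space)
# genotype label as published, `expected` the KASP-space call state
# counted as a match (these differ for BTS1161, whose KASP and NextRAD
# allele labels diverge; no strand conversion is guessed). The BTS46-203
# and BTS1161 rows cover only their SSA-ESA/SSA-CA scope (45 samples);
# class sizes at BTS141 are as published and include reference calls
# absent from the haplogroup-level table.
marker,class,ref_groups,n_class,expected,observed_state,count,mismatch_origin
BTS99-319,A:A,SSA-ECA/SSA-WA,73,A:A,A:A,73,
BTS99-319,G:G,SSA-ESA/SSA-CA/SSA2/SSA4,79,G:G,G:G,78,
BTS99-319,G:G,SSA-ESA/SSA-CA/SSA2/SSA4,79,G:G,A:A,1,Malawi
BTS22-762,G:G,SSA-WA,41,G:G,G:G,41,
BTS22-762,A:A,SSA-ECA,32,A:A,A:A,31,
BTS22-762,A:A,SSA-ECA,32,A:A,G:G,1,Kenya
BTS141,T:T,SSA2/SSA4,35,T:T,T:T,34,
BTS141,T:T,SSA2/SSA4,35,T:T,C:T,1,DRC
BTS141,C:C,SSA-ECA/SSA-WA/SSA-CA/SSA-ESA,117,C:C,C:C,117,
BTS55-473,T:T,SSA2,26,T:T,T:T,26,
BTS55-473,C:C,SSA4,8,C:C,C:C,8,
BTS613,G:G/G:A,SSA-ESA/SSA-CA,45,G:G,G:G,45,
BTS613,A:A,SSA-ECA/SSA-WA/SSA2/SSA4,107,A:A,A:A,107,
BTS46-203,A:A,SSA-ESA,41,A:A,A:A,39,
BTS46-203,A:A,SSA-ESA,41,A:A,A:G,2,Kenya; Tanzania
BTS46-203,G:G,SSA-CA,4,G:G,G:G,2,
BTS46-203,G:G,SSA-CA,4,G:G,A:G,2,DRC
BTS1161,A:A,SSA-ESA,41,C:C,C:C,33,
BTS1161,A:A,SSA-ESA,41,C:C,C:A,8,Malawi; Mozambique
BTS1161,G:G,SSA-CA,4,A:A,A:A,4,
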