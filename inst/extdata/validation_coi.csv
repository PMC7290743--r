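# Legacy COI barcode labels vs reference (NextRAD) haplogroups for the
# 152-sample validation cohort, aggregated per (COI label, haplogroup)
# pair. The published per-sample appendix is not redistributed; this
# table is a count-level reconstruction consistent with the published
# misidentification arithmetic (28/152 = 18.4%). The two SSA-CA samples
# counted as correctly identified carry the placeholder label "unknown"
# (no COI label uniquely indicates SSA-CA; see package vignette).
coi,ref_group,n
SSA1-SG1,SSA-ECA,24
SSA1-SG2,SSA-ECA,7
SSA1-SG1/SG2,SSA-ECA,1
SSA1-SG5,SSA-WA,27
SSA1-SG1,SSA-WA,13
SSA2,SSA-WA,1
SSA1-SG3,SSA-ESA,41
SSA1-SG1,SSA-CA,2
unknown,SSA-CA,2
SSA2,SSA2,22
SSA3,SSA2,3
SSA4,SSA2,1
SSA4,SSA4,8
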