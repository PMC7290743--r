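# Published haplogroup-level validation counts for the cassava Bemisia
# tabaci KASP panel: 152 field samples from 12 sub-Saharan African
# countries, assayed with the seven-marker panel and compared with
# reference (NextRAD) haplogroups. One SSA-ECA sample was assigned
# SSA-WA; all others matched (151/152).
ref_group,assignment,n
SSA-ECA,SSA-ECA,31
SSA-ECA,SSA-WA,1
SSA-WA,SSA-WA,41
SSA-CA,SSA-CA,4
SSA-ESA,SSA-ESA,41
SSA2,SSA2,26
SSA4,SSA4,8
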