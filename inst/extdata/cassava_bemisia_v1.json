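{
  "name": "cassava-bemisia-v1",
  "version": "1",
  "groups": [
    "SSA-ECA",
    "SSA-WA",
    "SSA-ESA",
    "SSA-CA",
    "SSA2",
    "SSA4"
  ],
  "markers": [
    {
      "marker_id": "BTS99-319",
      "allele_x": "A",
      "allele_y": "G",
      "scope": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA",
        "SSA2",
        "SSA4"
      ],
      "groups_x": [
        "SSA-ECA",
        "SSA-WA"
      ],
      "groups_y": [
        "SSA-ESA",
        "SSA-CA",
        "SSA2",
        "SSA4"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intergenic",
        "accession": "PGTP01000606.1",
        "amplicon_range": "849024-849984",
        "band_bp": 940,
        "pcr_f": "TTTCTGGAGGTATGATGTT",
        "pcr_r": "GTTGGCTTGTTTTTCTTTG",
        "kasp_allele_x": "CTCAAATTTAAAATACGATTTCAATTACCATT",
        "kasp_allele_y": "CTCAAATTTAAAATACGATTTCAATTACCATC",
        "kasp_common": "GCTGCATATTATACCGCATGAAAGCTAAA",
        "gateway": true
      }
    },
    {
      "marker_id": "BTS22-762",
      "allele_x": "A",
      "allele_y": "G",
      "scope": [
        "SSA-ECA",
        "SSA-WA"
      ],
      "groups_x": [
        "SSA-ECA"
      ],
      "groups_y": [
        "SSA-WA"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "Ssa12858; exon",
        "accession": "PGTP01001647.1",
        "amplicon_range": "62324-63244",
        "band_bp": 880,
        "pcr_f": "CAAACGAACACAACCGCAA",
        "pcr_r": "CAGGGACGTACACAAAATAA",
        "kasp_allele_x": "CAGTCAATTAAAAGACGTCTCGCTAA",
        "kasp_allele_y": "CAGTCAATTAAAAGACGTCTCGCTAG",
        "kasp_common": "GTCGCTGTCTTGTTTTCCCTCCAT"
      }
    },
    {
      "marker_id": "BTS141",
      "allele_x": "T",
      "allele_y": "C",
      "scope": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA",
        "SSA2",
        "SSA4"
      ],
      "groups_x": [
        "SSA2",
        "SSA4"
      ],
      "groups_y": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intergenic",
        "accession": "PGTP01000392.1",
        "amplicon_range": "896170-897370",
        "band_bp": 1150,
        "pcr_f": "TCCTCAGCAGTGTCTTTT",
        "pcr_r": "TCTACGTTGTGTTGTCGG",
        "kasp_allele_x": "TACTATTTCTAGCAAAGCGAATTTAAATCATA",
        "kasp_allele_y": "CTATTTCTAGCAAAGCGAATTTAAATCATG",
        "kasp_common": "GGAGTGCTATAAAGCGACCTATATGTAT"
      }
    },
    {
      "marker_id": "BTS55-473",
      "allele_x": "T",
      "allele_y": "C",
      "scope": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA",
        "SSA2",
        "SSA4"
      ],
      "groups_x": [
        "SSA2"
      ],
      "groups_y": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA",
        "SSA4"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intergenic",
        "accession": "PGTP01143321.1",
        "amplicon_range": "559651-560491",
        "band_bp": 815,
        "pcr_f": "ACCCCACCAAATATCTCAC",
        "pcr_r": "GGCATTCCAGCAAAATATACA",
        "kasp_allele_x": "CCGCACAGGAGACCCAAGTC",
        "kasp_allele_y": "ACCGCACAGGAGACCCAAGTT",
        "kasp_common": "TAATAAGCCCGACATGCCGCTCTTT"
      }
    },
    {
      "marker_id": "BTS613",
      "allele_x": "G",
      "allele_y": "A",
      "scope": [
        "SSA-ECA",
        "SSA-WA",
        "SSA-ESA",
        "SSA-CA",
        "SSA2",
        "SSA4"
      ],
      "groups_x": [
        "SSA-ESA",
        "SSA-CA"
      ],
      "groups_y": [
        "SSA-ECA",
        "SSA-WA",
        "SSA2",
        "SSA4"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intergenic",
        "accession": "PGTP01000317.1",
        "amplicon_range": "28760-29515",
        "band_bp": 730,
        "pcr_f": "CATTCCGCTTTCCATCCTC",
        "pcr_r": "CCTTCTCTTGTCGAACAT",
        "kasp_allele_x": "GGTAGAGCGGCGCTTGGTC",
        "kasp_allele_y": "ATGGTAGAGCGGCGCTTGGTT",
        "kasp_common": "ACTTCGGCTTTGAACTTCCCGCAAA"
      }
    },
    {
      "marker_id": "BTS46-203",
      "allele_x": "A",
      "allele_y": "G",
      "scope": [
        "SSA-ESA",
        "SSA-CA"
      ],
      "groups_x": [
        "SSA-ESA"
      ],
      "groups_y": [
        "SSA-CA"
      ],
      "fallback": "BTS1161",
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intron of Ssa00724",
        "accession": "PGTP01000379.1",
        "amplicon_range": "1505366-1505786",
        "band_bp": 390,
        "pcr_f": "CGAGGGCTAAAGAATAATAC",
        "pcr_r": "TTCAGAACGAATGAGAAGG",
        "kasp_allele_x": "GGTGCATCGTATCGCATCTCTGA",
        "kasp_allele_y": "GTGCATCGTATCGCATCTCTGG",
        "kasp_common": "CATATAACTACGCGCAACGCAACGTA"
      }
    },
    {
      "marker_id": "BTS1161",
      "allele_x": "C",
      "allele_y": "A",
      "scope": [
        "SSA-ESA",
        "SSA-CA"
      ],
      "groups_x": [
        "SSA-ESA"
      ],
      "groups_y": [
        "SSA-CA"
      ],
      "fallback": null,
      "contig": null,
      "pos": null,
      "metadata": {
        "gene_context": "intron of Ssa00849",
        "accession": "PGTP01001427.1",
        "amplicon_range": "371644-372644",
        "band_bp": 500,
        "pcr_f": "TTATTTTCGGTGGTGCGTC",
        "pcr_r": "GATGATGAGGGTAGAGTT",
        "kasp_allele_x": "AAGTCTTGCTGCTATGGCTTAGTTC",
        "kasp_allele_y": "AAAGTCTTGCTGCTATGGCTTAGTTA",
        "kasp_common": "CCCCATGTAGAGCTCCAGGTAAAAT",
        "nextrad_alleles": {
          "SSA-ESA": "A:A",
          "SSA-CA": "G:G"
        },
        "note": "KASP-space alleles (C = SSA-ESA, A = SSA-CA) differ from the reference-method allele labels stored in nextrad_alleles; no strand conversion is assumed."
      }
    }
  ],
  "tree": {
    "marker": "BTS99-319",
    "confirmation": [],
    "fallback": null,
    "edges": {
      "X": {
        "marker": "BTS22-762",
        "confirmation": [],
        "fallback": null,
        "edges": {
          "X": {
            "leaf": "SSA-ECA"
          },
          "Y": {
            "leaf": "SSA-WA"
          }
        }
      },
      "Y": {
        "marker": "BTS141",
        "confirmation": [
          "BTS613"
        ],
        "fallback": "BTS613",
        "edges": {
          "X": {
            "marker": "BTS55-473",
            "confirmation": [],
            "fallback": null,
            "edges": {
              "X": {
                "leaf": "SSA2"
              },
              "Y": {
                "leaf": "SSA4"
              }
            }
          },
          "Y": {
            "marker": "BTS46-203",
            "confirmation": [
              "BTS1161"
            ],
            "fallback": "BTS1161",
            "edges": {
              "X": {
                "leaf": "SSA-ESA"
              },
              "Y": {
                "leaf": "SSA-CA"
              }
            }
          }
        }
      }
    }
  },
  "provenance": {
    "description": "Seven-marker KASP panel distinguishing the six genome-wide SNP haplogroups of cassava-colonising Bemisia tabaci in sub-Saharan Africa.",
    "reference_genome": "GenBank PGTP01000000 (B. tabaci SSA1 SSA-ECA assembly)",
    "tree_note": "Decision key built greedily from the markers in published order; branch order within the non-ECA/WA side is a reconstruction of the published flow chart."
  }
}
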