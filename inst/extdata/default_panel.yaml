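# Extended RAS/BRAF hotspot panel: 13 codons, 39 coding positions.
# Coordinates are 1-based CDS positions on the coding strand; each codon's
# reference triplet is given explicitly so no sequence fetch is needed.
genes:
  - gene: KRAS
    codons: [12, 13, 59, 61, 117, 146]
    codon_sequences:
      "12": GGT
      "13": GGC
      "59": GCA
      "61": CAA
      "117": AAA
      "146": GCA
  - gene: NRAS
    codons: [12, 13, 59, 61, 117, 146]
    codon_sequences:
      "12": GGT
      "13": GGT
      "59": GCT
      "61": CAA
      "117": AAG
      "146": GCC
  - gene: BRAF
    codons: [600]
    codon_sequences:
      "600": GTG
# Positions excluded from evaluation: systematic PCR/sequencing artifacts
# (dominant G>A channel) found during calibration on normal samples.
excluded_sites: ["KRAS 37G", "KRAS 175G", "NRAS 351G"]
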