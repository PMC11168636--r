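{
  "_comment": [
    "Default peptide-binding-region codon mask for a class II B exon-2",
    "fragment read in frame 0. The 0-based codon indices follow the",
    "classical human DRB beta-1 peptide-binding positions (antigen-contact",
    "residues of the crystal-structure lineage), restricted to the first 99",
    "codons of the fragment. This is an interpretation intended as an",
    "editable starting point: studies should replace it with the mask",
    "appropriate to their alignment and numbering."
  ],
  "frame_offset": 0,
  "pbr_codons": [8, 10, 12, 25, 27, 29, 31, 36, 37, 46, 55, 56, 59, 60, 64,
                 66, 67, 69, 70, 73, 77, 80, 81, 84, 85]
}
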