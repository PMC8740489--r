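# Demo partial-protocol config: per-gene primer end positions are
# IMGT-numbering coordinates; genes absent from the map cannot be
# amplified by this design.
name: biomed2
per_gene_primer_end:
  TRBV91-1: 8
  TRBV91-2: 8
j_anchor_length: null
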