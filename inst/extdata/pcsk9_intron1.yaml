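# Synthetic splice-donor fixture: target +6, bystander adenine at -1. The -1
# codon context is a synthetic stand-in (the real context is intronic).
name: pcsk9_intron1
editable_positions: [-1, 6]
target_position: 6
consequences:
  - {position: -1, ref_codon: AGT, edited_codon: GGT}
  - {position: 6, ref_codon: ACG, edited_codon: GCG}
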