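# Synthetic sickle-allele fixture: target adenine +7, synonymous bystanders
# at +9 and +12.
name: hbb_s
editable_positions: [7, 9, 12]
target_position: 7
consequences:
  - {position: 7, ref_codon: ACA, edited_codon: GCA}
  - {position: 9, ref_codon: ACA, edited_codon: ACG}
  - {position: 12, ref_codon: CCA, edited_codon: CCG}
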