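# Synthetic HFE C282Y correction fixture: target adenine at +5, missense-risk
# bystanders at +1 and +8.
name: hfe_c282y
editable_positions: [1, 5, 8]
target_position: 5
consequences:
  - {position: 1, ref_codon: ACG, edited_codon: GCG}
  - {position: 5, ref_codon: TAC, edited_codon: TGC}
  - {position: 8, ref_codon: CAG, edited_codon: CGG}
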