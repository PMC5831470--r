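# Default prohormone-convertase cleavage rule table (editable copy of the
# built-in default_cleavage_rules()). Tiers are mono-/dibasic motif classes;
# needs_upstream_basic demands K/R at one of upstream_offsets relative to the
# cleaved residue. Exclusions apply to every tier except those in 'exempt'.
tiers:
  - motif_class: KR
    needs_upstream_basic: false
    confidence: high
  - motif_class: RR
    needs_upstream_basic: false
    confidence: medium
  - motif_class: KK
    needs_upstream_basic: true
    confidence: low
  - motif_class: RK
    needs_upstream_basic: true
    confidence: low
  - motif_class: monoR
    needs_upstream_basic: true
    confidence: medium
upstream_offsets: [-3, -5, -7]
exclusions:
  proline_window_n: 2
  proline_p1prime: true
  cys_radius: 3
  exempt: KR
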