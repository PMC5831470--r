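# Neuropeptide family motif registry.
# Terminal consensus patterns (c_pattern anchored at the C-terminus,
# n_pattern at the N-terminus) with PTM expectations. Patterns use literal
# residues, '.' (any) and single-position character classes. requires_amide /
# requires_pq omitted = indifferent. min_cys demands that many cysteines.
families:
  - family: ACP
    c_pattern: "GWGP"
    requires_amide: true
    requires_pq: true
  - family: AKH
    c_pattern: "STGW"
    requires_amide: true
    requires_pq: true
    max_len: 12
  - family: AST-A
    c_pattern: "[FY]G[LIV]"
    requires_amide: true
  - family: AST-CC
    c_pattern: "NAVTCF"
    requires_amide: false
    min_cys: 2
  - family: AST-CCC
    c_pattern: "NAVSCF"
    requires_amide: false
    min_cys: 2
  - family: AT
    n_pattern: "G..P"
    c_pattern: "F"
    requires_amide: true
    min_len: 12
  - family: AVLP
    c_pattern: "CPRG"
    requires_amide: true
    min_cys: 2
  - family: CCAP
    c_pattern: "NAFTGC"
    requires_amide: true
    min_cys: 2
  - family: CCHa-1
    c_pattern: "GHSCWG[AG]H"
    requires_amide: true
    min_cys: 2
  - family: CCHa-2
    c_pattern: "GHSC[YF]GGH"
    requires_amide: true
    min_cys: 2
  - family: CNMa
    c_pattern: "CNM"
    requires_amide: true
  - family: CRZ
    c_pattern: "GWT[NT]"
    requires_amide: true
    requires_pq: true
  - family: DH31
    c_pattern: "AGGP"
    requires_amide: true
    min_len: 20
  - family: DH44
    n_pattern: "I.SLS"
    requires_amide: true
    min_len: 35
  - family: ELN
    c_pattern: "CRG..."
    requires_amide: false
    min_cys: 2
  - family: ETH
    c_pattern: "KN[IV]PRI"
    requires_amide: true
  - family: FMRFa
    c_pattern: "[IV]R[FY]"
    requires_amide: true
  - family: ITG
    n_pattern: "IT[GQ]"
    requires_amide: false
  - family: kinin
    c_pattern: "[NSP]WG"
    requires_amide: true
  - family: MS
    c_pattern: "FLRF"
    requires_amide: true
    requires_pq: true
  - family: NTL
    c_pattern: "PF...R"
    requires_amide: true
  - family: NPF
    c_pattern: "KAR[FY]"
    requires_amide: true
    min_len: 25
  - family: NPLP1
    n_pattern: ".[ILV][AG][SAGT][LM][AG][KR]"
  - family: OK-A
    n_pattern: "N[FI]DEIDR"
    requires_amide: false
  - family: OK-B
    n_pattern: "NLD[HQ]IGGGNL"
    requires_amide: false
  - family: PDF
    c_pattern: "MNNA"
    requires_amide: true
  - family: PVK
    c_pattern: "[YQ]PR[VI]"
    requires_amide: true
  - family: PK
    c_pattern: ".PRL"
    requires_amide: true
  - family: trypto-PK
    c_pattern: "WFGPRL"
    requires_amide: true
  - family: RYa
    c_pattern: "[GSA]R[FY]"
    requires_amide: true
  - family: SIFa
    c_pattern: "PPFNGSIF"
    requires_amide: true
  - family: sNPF
    c_pattern: "RSPS[LY]RLRF"
    requires_amide: true
  - family: SK
    c_pattern: "GHMRF"
    requires_amide: true
  - family: TK
    c_pattern: "G[MVT]R"
    requires_amide: true
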