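# allele-site sidecar for the knock-in donor amplicon (1-based, top strand)
sites:
  - {offset: 41, wt_base: C, mut_base: A, role: marker}
  - {offset: 61, wt_base: G, mut_base: C, role: pathogenic}
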