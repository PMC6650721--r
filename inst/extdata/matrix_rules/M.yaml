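# pan-taxon supermatrix: genes with at least 100 represented taxa,
# optionally reduced to the top information-rich subset
build:
  label: M
  minTaxa: 100
  # rankTop: 422
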