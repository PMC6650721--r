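# spiralian matrix: combined minimum over two rare clades
# (use two separate entries instead for the per-clade reading)
build:
  label: S
  minTaxa: 50
  cladeMinima:
    - clades: [Entoprocta, Cycliophora]
      min: 3
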