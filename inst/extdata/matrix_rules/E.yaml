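# clade-focused matrix for sparsely sampled moulting-animal phyla:
# at least two representatives of each listed clade, then rank-and-cut
build:
  label: E
  minTaxa: 50
  cladeMinima:
    - clades: [Kinorhyncha]
      min: 2
    - clades: [Loricifera]
      min: 2
    - clades: [Nematomorpha]
      min: 2
  rankTop: 445
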