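# deep-animal matrix: a required taxon plus per-clade minima, then
# rank-and-cut
build:
  label: N
  minTaxa: 50
  requiredTaxa: [Trichoplax_adhaerens]
  cladeMinima:
    - clades: [Choanoflagellata]
      min: 1
    - clades: [Porifera]
      min: 6
    - clades: [Ctenophora]
      min: 3
    - clades: [Cnidaria]
      min: 4
  rankTop: 264
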