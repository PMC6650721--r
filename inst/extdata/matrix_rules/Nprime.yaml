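# as N, built after deleting all non-choanoflagellate outgroup taxa from
# the inputs (taxon deletion precedes trimming; see the methods vignette
# on why deletion order changes how many sites survive)
build:
  label: Nprime
  minTaxa: 39
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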