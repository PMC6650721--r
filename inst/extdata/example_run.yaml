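# 16-taxon simulated end-to-end run: species tree + gene families ->
# grooming -> orthology -> supermatrix -> trimming -> chain diagnostics
seed: 42
stages: [simulate, groom, ortho, build, trim, diagnose]
simulate:
  nTaxa: 16
  nGenes: 30
  nSites: 600
  yuleRate: 8
  dupRate: 0.05
  lossRate: 0.05
  chains:
    nChains: 4
    nSamples: 500
    scatterProb: 0.1
    rogueTaxon: t9
build:
  label: M
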