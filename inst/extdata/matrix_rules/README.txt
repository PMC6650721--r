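Example gene-selection rule sets for the five matrix styles the pipeline
supports (labels M, E, S, N, Nprime). Each YAML fragment is a `build:`
section for runPipeline(); clade labels must exist in the run's clade map,
and required taxa must match its taxon names. Gene counts are whatever the
rules select on the data at hand.

M      pan-taxon matrix: plain occupancy floor, optional top-k ranking
E      ecdysozoan matrix: per-clade minima for sparsely sampled phyla
S      spiralian matrix: combined minimum over Entoprocta + Cycliophora
N      deep-animal matrix: required taxon plus per-clade minima
Nprime N after outgroup deletion (same rules; drop taxa before building)
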