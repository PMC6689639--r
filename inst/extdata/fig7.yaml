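# Modified lottery ML(A) with linked open-science improvements p = r.
conditions:
  - {strategy: ML, A: 0.1, p: 0.0, r: 0.0}
  - {strategy: ML, A: 0.3, p: 0.0, r: 0.0}
  - {strategy: ML, A: 0.6, p: 0.0, r: 0.0}
  - {strategy: ML, A: 1.0, p: 0.0, r: 0.0}
  - {strategy: ML, A: 0.1, p: 0.25, r: 0.25}
  - {strategy: ML, A: 0.3, p: 0.25, r: 0.25}
  - {strategy: ML, A: 0.6, p: 0.25, r: 0.25}
  - {strategy: ML, A: 1.0, p: 0.25, r: 0.25}
  - {strategy: ML, A: 0.1, p: 0.5, r: 0.5}
  - {strategy: ML, A: 0.3, p: 0.5, r: 0.5}
  - {strategy: ML, A: 0.6, p: 0.5, r: 0.5}
  - {strategy: ML, A: 1.0, p: 0.5, r: 0.5}
replicates: 5
seed_base: 1
iterations: 100000
equilibrium_window: 10000
base:
  G: 10
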