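# Mixed strategy MS(X) with linked open-science improvements p = r.
conditions:
  - {strategy: MS, X: 0.0, p: 0.0, r: 0.0}
  - {strategy: MS, X: 0.2, p: 0.0, r: 0.0}
  - {strategy: MS, X: 0.5, p: 0.0, r: 0.0}
  - {strategy: MS, X: 1.0, p: 0.0, r: 0.0}
  - {strategy: MS, X: 0.0, p: 0.25, r: 0.25}
  - {strategy: MS, X: 0.2, p: 0.25, r: 0.25}
  - {strategy: MS, X: 0.5, p: 0.25, r: 0.25}
  - {strategy: MS, X: 1.0, p: 0.25, r: 0.25}
  - {strategy: MS, X: 0.0, p: 0.5, r: 0.5}
  - {strategy: MS, X: 0.2, p: 0.5, r: 0.5}
  - {strategy: MS, X: 0.5, p: 0.5, r: 0.5}
  - {strategy: MS, X: 1.0, p: 0.5, r: 0.5}
replicates: 5
seed_base: 1
iterations: 100000
equilibrium_window: 10000
base:
  G: 10
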