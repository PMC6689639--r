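# Interaction of publication bias and peer review, small and large grants.
axes:
  strategy: [RA, MI]
  p: [0, 0.5, 1]
  r: [0, 0.5, 1]
  G: [10, 85]
replicates: 5
seed_base: 1
iterations: 100000
equilibrium_window: 10000
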