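# Publishing negative results at increasing rates (r = 0).
axes:
  strategy: [PH, RA, MI]
  p: [0, 0.25, 0.5, 0.75, 1]
replicates: 5
seed_base: 1
iterations: 100000
equilibrium_window: 10000
base:
  r: 0
  G: 10
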