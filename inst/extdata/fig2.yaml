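# Pure funding strategies without open-science improvements (p = r = 0),
# across grant sizes. Reduced scale: 1e5 iterations, 5 replicates.
axes:
  strategy: [PH, RA, MI]
  G: [10, 85]
replicates: 5
seed_base: 1
iterations: 100000
equilibrium_window: 10000
base:
  p: 0
  r: 0
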