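# Synthetic survey emulating a grid-random urban-forest plot inventory.
# Any field omitted here falls back to the package defaults.
seed: 42
transform: log
synthetic:
  region: {origin_x: 0, origin_y: 0, width_m: 30000, height_m: 35000}
  design: {cell_size_m: 2500, n_target: 120, exclusion_fraction: 0.2}
kriging:
  cell_size_m: 1500
  holdout_fraction: 0.1
geodetector:
  k: 5
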