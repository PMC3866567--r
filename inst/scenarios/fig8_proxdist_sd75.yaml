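name: fig8_proxdist_sd75
layers: [L5]
duration: 550.0
dt: 0.025
window: [50.0, 550.0]
seed: 42
network:
  L5: {g_ei: 9.1e-4, g_ie: 8.0e-2, g_ii: 7.5e-3, space_constant: 3.5, regime: subthreshold}
drives:
  - {type: burst, input_class: proximal, f: 50.0, sigma: 2.5, events_per_cycle: 10, g_max: 4.0e-5, layer: L5}
  - {type: burst, input_class: distal, f: 50.0, sigma: 7.5, events_per_cycle: 10, g_max: 4.0e-5, lag: 5.0, layer: L5}
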