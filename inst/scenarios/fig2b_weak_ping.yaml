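name: fig2b_weak_ping
layers: [L5]
duration: 550.0
dt: 0.025
window: [50.0, 550.0]
seed: 42
network:
  L5: {g_ei: 9.1e-4, g_ie: 8.0e-2, g_ii: 7.5e-3, space_constant: 3.5, regime: weak PING}
drives:
  - {type: poisson, rate: 40.0, g_max: 7.5e-3, layer: L5}
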