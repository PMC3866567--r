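name: fig5a_l2_weak_ping
layers: [L2]
duration: 550.0
dt: 0.025
window: [50.0, 550.0]
seed: 42
network:
  L2: {g_ei: 1.2e-3, g_ie: 7.0e-3, g_ii: 1.0e-2, space_constant: 3.5, regime: weak PING}
drives:
  - {type: poisson, rate: 140.0, g_max: 8.0e-4, layer: L2}
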