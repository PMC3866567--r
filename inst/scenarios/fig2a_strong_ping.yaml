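name: fig2a_strong_ping
layers: [L5]
duration: 550.0
dt: 0.025
window: [50.0, 550.0]
seed: 42
network:
  L5: {g_ei: 6.0e-5, g_ie: 0.3, g_ii: 0.0, space_constant: 2.5, regime: strong PING}
drives:
  - {type: tonic, i_app: 6.0, layer: L5}
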