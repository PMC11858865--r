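mode: dlm
compound:
  vc: 140.0
  vp: 1500.0
  q_dist: 50.0
  clint_3a4: 20000.0
  clint_3a5: 0.0
  fu_plasma: 0.01
  q_h: 90.0
  peff: 1.2
  bp_max: 35.0
  c50: 5.0
  k_villi: 4.0
  kgut_3a4: 4.0
  kgut_3a5: 0.0
formulation:
  dose: 5.0
  density: 1.3
  diffusivity: 5.0e-06
  radius_um: 10.0
  weights: 1.0
  hmax: 30.0
  dlm_scalars: []
protocol:
  cell_volume: 20.0
  segments:
  - medium: FaSSGF
    start: 0.0
    duration: 30.0
    flow_rate: 8.0
  - medium: FaSSIF-V2
    start: 30.0
    duration: 40.0
    flow_rate: 4.0
  - medium: FaSSIF-V2 midgut
    start: 70.0
    duration: 80.0
    flow_rate: 4.0
  - medium: SIF Ileum-V2
    start: 150.0
    duration: 60.0
    flow_rate: 4.0
  - medium: FaSSCoF
    start: 210.0
    duration: 150.0
    flow_rate: 4.0
  media:
    FaSSGF:
      pH: 1.6
      buffer_total: 0.0
      buffer_pka1: .na.real
      buffer_pka2: .na.real
      bile_salt: 0.08
      solubility: 0.025
    FaSSIF-V2:
      pH: 6.5
      buffer_total: 19.1
      buffer_pka1: 1.83
      buffer_pka2: 5.99
      bile_salt: 3.0
      solubility: 0.05
    FaSSIF-V2 midgut:
      pH: 6.8
      buffer_total: 19.3
      buffer_pka1: 1.83
      buffer_pka2: 5.99
      bile_salt: 1.5
      solubility: 0.045
    SIF Ileum-V2:
      pH: 7.5
      buffer_total: 52.8
      buffer_pka1: 1.83
      buffer_pka2: 5.99
      bile_salt: 0.8
      solubility: 0.035
    FaSSCoF:
      pH: 7.8
      buffer_total: 75.8
      buffer_pka1: 1.83
      buffer_pka2: 5.99
      bile_salt: 0.0
      solubility: 0.02
trial:
  n_subjects: 12.0
  cv:
    clint: 0.3
    vc: 0.25
    peff: 0.3
  residual_cv: 0.1
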