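# ssDNA pulled through two SSB-like binding modes (65 nt and 35 nt site
# sizes). Polymer elastic parameters are of the order of those of ssDNA.
polymer:
  N: 5080
  d0: 0.57
  Lp: 0.715
  K0: 700.0
  kBT: 4.11
modes:
  - label: mode1
    m: 65
    a: 5.0
    eps_b: 133.575   # 0.5 * m * kBT
    kb: 1.0
    kr: 1.0e-5
  - label: mode2
    m: 35
    a: 5.0
    eps_b: 71.925    # 0.5 * m * kBT
    kb: 0.0
    kr: 1.0e-5
kinetics:
  s: 2
  k12: 1.0e-3
  k21: 5.0e-5
generation:
  fmin: 0.01
  fmax: 100.0
  points: 200
  noise_sd: 2.0
  seed: 42
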