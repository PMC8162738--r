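unit_cell:
  a1:
  - 2.1739
  - 0.0
  a2:
  - 0.4188
  - 0.7838
  basis:
  - frac1: 0.0
    frac2: 0.0
    angle: 8.0
    tilt: 0.0
  - frac1: 0.5
    frac2: 0.5
    angle: -8.0
    tilt: 0.0
walls:
  r_iw: 3.2
  r_ow: 5.7
  theta: 30.0
  tube_length: 15.0
  ow_scale: 1.024
extended_dipole:
  q: 0.34
  l: 0.7
monomer:
  e0: 19498.0
disorder:
  sigma_pos: 0.05
  sigma_orient: 5.0
  diagonal:
    mean_iw: 350.0
    mean_ow: 350.0
    sigma_iw: 213.0
    sigma_ow: 231.0
  n_snapshots: 20.0
broadening:
  fwhm: 150.0
  lineshape: lorentzian
scan:
  thetas:
  - 20.0
  - 30.0
  - 40.0
  - 55.0
  factors:
  - 1.0
  - 1.005
  - 1.01
  - 1.015
  - 1.02
  - 1.025
  - 1.03
  - 1.035
  - 1.04
  - 1.045
  - 1.05
seed: 1.0
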