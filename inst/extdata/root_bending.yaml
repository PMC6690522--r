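# Anisotropic elongation ("root bending") reference configuration.
# A 76 x 32 um tissue slab elongating only along x, with the growth rate
# increasing linearly from the bottom to the top border; the slow side
# becomes the inner side of the emerging arc.
mesh:
  width: 76
  height: 32
  L0: 1
material:
  Yx: 40
  Yy: 80
  nu: 0.2
  pt: 0.2
solver:
  hgamma: 0.01
  mass: 1
  eta: 1
  thr: 0.05
growth:
  kind: linear-gradient-y
  kx: 0.00479
  ky: 0
  frac_min: 0.25
  ht: 1
  duration: 141
output:
  format: csv
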