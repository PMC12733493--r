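# Solvent model catalogue.
#
# Units: charge e, sigma A, epsilon kcal/mol, position A (rigid molecular
# frame), density molecules/A^3, temperature K.
#
# Geometry for both entries: l(O-H) = 1.0 A, HOH angle 109.47 deg
# (tetrahedral), so l(H-H) = 1.633 A.  Density 0.03332 / A^3 is
# 0.997 g/cm^3 at 298.15 K.
#
# spce  — standard SPC/E (hydrogens are bare charges, no LJ core).
# mspce — modified SPC/E for integral-equation work: identical charges
#         and oxygen LJ, plus a small hydrogen LJ core
#         (sigma 1.0 A, epsilon 0.0545 kcal/mol) that keeps the
#         site-site closures regular at the O-H contact.

spce:
  density: 0.03332
  temperature: 298.15
  dielectric: 78.4
  sites:
    - {name: Ow, charge: -0.8476, sigma: 3.166, epsilon: 0.1553,
       position: [0.0, 0.0, 0.0]}
    - {name: Hw, charge: 0.4238, sigma: 0.0, epsilon: 0.0,
       position: [0.8164966, 0.5773503, 0.0]}
    - {name: Hw, charge: 0.4238, sigma: 0.0, epsilon: 0.0,
       position: [-0.8164966, 0.5773503, 0.0]}

mspce:
  density: 0.03332
  temperature: 298.15
  dielectric: 78.4
  sites:
    - {name: Ow, charge: -0.8476, sigma: 3.166, epsilon: 0.1553,
       position: [0.0, 0.0, 0.0]}
    - {name: Hw, charge: 0.4238, sigma: 1.0, epsilon: 0.0545,
       position: [0.8164966, 0.5773503, 0.0]}
    - {name: Hw, charge: 0.4238, sigma: 1.0, epsilon: 0.0545,
       position: [-0.8164966, 0.5773503, 0.0]}
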