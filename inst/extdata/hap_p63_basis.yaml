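# 44-atom hexagonal P6_3 hydroxyapatite basis, Ca10(PO4)6(OH)2.
# Fractional coordinates assembled from the standard P6_3/m
# single-crystal refinement (Hughes et al., Am. Mineral. 74, 1989),
# with the half-occupied hydroxyl site resolved to the ordered
# P6_3 arrangement: both OH groups parallel to +c. Editable config.
a: 9.417
b: 9.417
c: 6.875
gamma: 120.0
oh_orientation: ordered
basis:
  - [Ca, 0.333333, 0.666667, 0.001000]
  - [Ca, 0.666667, 0.333333, 0.501000]
  - [Ca, 0.666667, 0.333333, 0.999000]
  - [Ca, 0.333333, 0.666667, 0.499000]
  - [Ca, 0.246600, 0.993100, 0.250000]
  - [Ca, 0.006900, 0.253500, 0.250000]
  - [Ca, 0.746500, 0.753400, 0.250000]
  - [Ca, 0.753400, 0.006900, 0.750000]
  - [Ca, 0.993100, 0.746500, 0.750000]
  - [Ca, 0.253500, 0.246600, 0.750000]
  - [P, 0.398200, 0.368500, 0.250000]
  - [P, 0.631500, 0.029700, 0.250000]
  - [P, 0.970300, 0.601800, 0.250000]
  - [P, 0.601800, 0.631500, 0.750000]
  - [P, 0.368500, 0.970300, 0.750000]
  - [P, 0.029700, 0.398200, 0.750000]
  - [Op, 0.328300, 0.484600, 0.250000]
  - [Op, 0.515400, 0.843700, 0.250000]
  - [Op, 0.156300, 0.671700, 0.250000]
  - [Op, 0.671700, 0.515400, 0.750000]
  - [Op, 0.484600, 0.156300, 0.750000]
  - [Op, 0.843700, 0.328300, 0.750000]
  - [Op, 0.587600, 0.465200, 0.250000]
  - [Op, 0.534800, 0.122400, 0.250000]
  - [Op, 0.877600, 0.412400, 0.250000]
  - [Op, 0.412400, 0.534800, 0.750000]
  - [Op, 0.465200, 0.877600, 0.750000]
  - [Op, 0.122400, 0.587600, 0.750000]
  - [Op, 0.343600, 0.257900, 0.070200]
  - [Op, 0.742100, 0.085700, 0.070200]
  - [Op, 0.914300, 0.656400, 0.070200]
  - [Op, 0.656400, 0.742100, 0.570200]
  - [Op, 0.257900, 0.914300, 0.570200]
  - [Op, 0.085700, 0.343600, 0.570200]
  - [Op, 0.656400, 0.742100, 0.929800]
  - [Op, 0.257900, 0.914300, 0.929800]
  - [Op, 0.085700, 0.343600, 0.929800]
  - [Op, 0.343600, 0.257900, 0.429800]
  - [Op, 0.742100, 0.085700, 0.429800]
  - [Op, 0.914300, 0.656400, 0.429800]
  - [Oh, 0.000000, 0.000000, 0.197900]
  - [Oh, 0.000000, 0.000000, 0.697900]
  - [Ho, 0.000000, 0.000000, 0.055355]
  - [Ho, 0.000000, 0.000000, 0.555355]
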