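# Default interaction parameters for hydroxyapatite plus 3-site water.
# This is a documented, self-consistent default set -- formal ionic charges
# partitioned over the phosphate (P +1.4, O -1.1 -> PO4 3-) and hydroxyl
# (O -1.425, H +0.425 -> OH 1-) groups with Ca 2+, conventional
# Lennard-Jones radii, and stiff harmonic bonds/angles -- not a fitted
# literature force field. Edit or replace this file to change the model;
# pair entries may select the 9-6 form per species pair.
species:
  Ca: {charge: 2.0,    mass: 40.078,    epsilon: 0.24, sigma: 2.90}
  P:  {charge: 1.4,    mass: 30.973762, epsilon: 0.20, sigma: 3.74}
  Op: {charge: -1.1,   mass: 15.999,    epsilon: 0.152, sigma: 3.15}
  Oh: {charge: -1.425, mass: 15.999,    epsilon: 0.152, sigma: 3.15}
  Ho: {charge: 0.425,  mass: 1.008,     epsilon: 0.0,  sigma: 0.8}
  Ow: {charge: -0.834, mass: 15.999,    epsilon: 0.152, sigma: 3.1507}
  Hw: {charge: 0.417,  mass: 1.008,     epsilon: 0.0,  sigma: 0.8}
pairs:
  # calcium-oxygen contacts use the softer 9-6 form
  - {a: Ca, b: Op, form: lj9-6, epsilon: 0.30, sigma: 3.20}
  - {a: Ca, b: Oh, form: lj9-6, epsilon: 0.30, sigma: 3.20}
bonds:
  Ho-Oh: {k: 553.0, r0: 0.96}
  Op-P:  {k: 525.0, r0: 1.54}
  Hw-Ow: {k: 553.0, r0: 0.9572}
angles:
  Op-P-Op: {k: 140.0, theta0: 109.47}
  Hw-Ow-Hw: {k: 100.0, theta0: 104.52}
cutoff: 10.0
shift: true
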