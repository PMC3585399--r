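# Dipolar ligand fragment definitions.
#
# Local frames place the coordinating point at the origin with +z pointing away
# from the ion. Charges in e; epsilon kcal/mol; rmin2 = Rmin/2 Angstrom; mass amu.
# Bond force constants k and angle force constants ka follow the 0.5*k*(delta)^2
# convention (kcal/mol/A^2 and kcal/mol/rad^2); theta0 in degrees. Stiffnesses are
# transcribed from an additive all-atom protein force field.
#
# formaldehyde_like: the abstract cage ligand (C +0.5, O -0.5, H 0.0).
formaldehyde_like:
  atoms:
    - {name: C,  element: C, charge:  0.5, eps: 0.110, rmin2: 2.000, mass: 12.011, x:  0.000, "y": 0.0, z: 1.230}
    - {name: O,  element: O, charge: -0.5, eps: 0.120, rmin2: 1.700, mass: 15.999, x:  0.000, "y": 0.0, z: 0.000}
    - {name: H1, element: H, charge:  0.0, eps: 0.022, rmin2: 1.320, mass: 1.008,  x:  0.942, "y": 0.0, z: 1.817}
    - {name: H2, element: H, charge:  0.0, eps: 0.022, rmin2: 1.320, mass: 1.008,  x: -0.942, "y": 0.0, z: 1.817}
  coordinating: [2]
  bonds:
    - {i: 1, j: 2, r0: 1.230, k: 1240.0}
    - {i: 1, j: 3, r0: 1.110, k: 660.0}
    - {i: 1, j: 4, r0: 1.110, k: 660.0}
  angles:
    - {i: 2, j: 1, k: 3, theta0: 121.9, ka: 100.0}
    - {i: 2, j: 1, k: 4, theta0: 121.9, ka: 100.0}
    - {i: 3, j: 1, k: 4, theta0: 116.2, ka: 90.0}

# backbone_carbonyl: same dipolar unit standing in for a peptide C=O with its
# two backbone neighbours reduced to hydrogens.
backbone_carbonyl:
  atoms:
    - {name: C,  element: C, charge:  0.5, eps: 0.110, rmin2: 2.000, mass: 12.011, x:  0.000, "y": 0.0, z: 1.230}
    - {name: O,  element: O, charge: -0.5, eps: 0.120, rmin2: 1.700, mass: 15.999, x:  0.000, "y": 0.0, z: 0.000}
    - {name: H1, element: H, charge:  0.0, eps: 0.022, rmin2: 1.320, mass: 1.008,  x:  0.942, "y": 0.0, z: 1.817}
    - {name: H2, element: H, charge:  0.0, eps: 0.022, rmin2: 1.320, mass: 1.008,  x: -0.942, "y": 0.0, z: 1.817}
  coordinating: [2]
  bonds:
    - {i: 1, j: 2, r0: 1.230, k: 1240.0}
    - {i: 1, j: 3, r0: 1.110, k: 660.0}
    - {i: 1, j: 4, r0: 1.110, k: 660.0}
  angles:
    - {i: 2, j: 1, k: 3, theta0: 121.9, ka: 100.0}
    - {i: 2, j: 1, k: 4, theta0: 121.9, ka: 100.0}
    - {i: 3, j: 1, k: 4, theta0: 116.2, ka: 90.0}

# hydroxyl: serine/threonine-like O-H with the attached carbon.
hydroxyl:
  atoms:
    - {name: O, element: O, charge: -0.65, eps: 0.1521, rmin2: 1.7700, mass: 15.999, x: 0.000, "y": 0.0, z:  0.000}
    - {name: H, element: H, charge:  0.43, eps: 0.0460, rmin2: 0.2245, mass: 1.008,  x: 0.923, "y": 0.0, z: -0.264}
    - {name: C, element: C, charge:  0.22, eps: 0.0800, rmin2: 2.0600, mass: 12.011, x: 0.000, "y": 0.0, z:  1.420}
  coordinating: [1]
  bonds:
    - {i: 1, j: 2, r0: 0.960, k: 1090.0}
    - {i: 1, j: 3, r0: 1.420, k: 856.0}
  angles:
    - {i: 2, j: 1, k: 3, theta0: 106.0, ka: 110.0}

# carboxylate: aspartate/C-terminal COO- with both oxygens coordinating
# (bidentate); the coordinating point is the midpoint of the two oxygens.
carboxylate:
  atoms:
    - {name: C,  element: C, charge:  0.52, eps: 0.070, rmin2: 2.000, mass: 12.011, x:  0.000, "y": 0.0, z: 0.601}
    - {name: O1, element: O, charge: -0.76, eps: 0.120, rmin2: 1.700, mass: 15.999, x:  1.107, "y": 0.0, z: 0.000}
    - {name: O2, element: O, charge: -0.76, eps: 0.120, rmin2: 1.700, mass: 15.999, x: -1.107, "y": 0.0, z: 0.000}
  coordinating: [2, 3]
  bonds:
    - {i: 1, j: 2, r0: 1.260, k: 1050.0}
    - {i: 1, j: 3, r0: 1.260, k: 1050.0}
  angles:
    - {i: 2, j: 1, k: 3, theta0: 123.0, ka: 200.0}
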