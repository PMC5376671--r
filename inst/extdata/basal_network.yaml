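# Calibrated basal Hoxa5/Hoxc8 network (mir-x present but unconnected; its
# candidate edges are added by instantiate_topology()). All quantities
# dimensionless; rates in 1/day. Calibration criterion: without mir-x edges,
# noisy RA/FGF gradients give overlapping, ragged and caudally expanded
# Hoxa5 expression; the consensus mir-x circuit sharpens the boundary and
# aligns it with the Hoxc8 boundary.
species:
- hoxa5_mRNA
- hoxa5_protein
- hoxc8_mRNA
- hoxc8_protein
- mir_x
sigma: 25.0
gamma:
  hoxa5_mRNA: 5.0
  hoxa5_protein: 5.0
  hoxc8_mRNA: 5.0
  hoxc8_protein: 2.0
  mir_x: 1.0
basal:
  hoxa5_mRNA: -0.08
  hoxa5_protein: -0.65
  hoxc8_mRNA: -0.102
  hoxc8_protein: -2.025
  mir_x: 0.1
edges:
- source: RA
  target: hoxa5_mRNA
  weight: 1.0
- source: hoxc8_protein
  target: hoxa5_mRNA
  weight: -0.15
- source: hoxa5_mRNA
  target: hoxa5_protein
  weight: 1.0
- source: FGF
  target: hoxc8_mRNA
  weight: 1.0
- source: hoxc8_mRNA
  target: hoxc8_protein
  weight: 4.5
clamp_zero: []
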