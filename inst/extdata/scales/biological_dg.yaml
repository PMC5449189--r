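# Biological hydrophobicity scale for translocon-mediated membrane insertion.
#
# Per-residue parameters of the position-dependent contribution to the
# apparent free energy of insertion (dG_app, kcal/mol) of a candidate
# transmembrane helix:
#
#   contrib(aa, z) = dg0 * exp(-width * z^2)
#                  + arom_dg * [exp(-arom_width * (z - arom_offset)^2) +
#                               exp(-arom_width * (z + arom_offset)^2)]
#
# where z is the residue position rescaled so that the helix spans [-9, 9]
# (the half-width of the 19-residue reference helix). dg0 is the
# contribution at the helix centre (z = 0), so the centre weight is 1 for
# every residue. The second (double-Gaussian) term applies to the aromatics
# W and Y only and models their preference for the interface region.
#
# The helix-length correction is the quadratic
#   q(L) = c0 + c1*L + c2*L^2, applied as dG_len(L) = q(L) - q(ref_length)
# so that it vanishes exactly at the reference length.
#
# Parameter values transcribe the published biological-scale model of
# translocon-mediated insertion; the file is versioned so that alternative
# transcriptions or scales can be swapped in without code changes. 'X'
# (unknown residue) contributes x_dg (default 0) and is flagged in output.
name: biological-dg
version: "1.0"
profile: gaussian
l_min: 19
l_max: 23
ref_length: 19
length_coeffs: [9.29, -0.645, 0.00822]
arom_offset: 6.27
x_dg: 0.0
residues:
  "A": {dg0:  0.1267255, width: 0.0215152}
  "C": {dg0: -0.0765051, width: 0.0994228}
  "D": {dg0:  1.7939795, width: 0.1704556}
  "E": {dg0:  1.4193720, width: 0.0894513}
  "F": {dg0: -0.2766953, width: 0.0010297}
  "G": {dg0:  0.4813492, width: 0.0047210}
  "H": {dg0:  1.1998590, width: 0.0080127}
  "I": {dg0: -0.4597384, width: 0.0181495}
  "K": {dg0:  1.8485768, width: 0.0218446}
  "L": {dg0: -0.4282992, width: 0.0023804}
  "M": {dg0: -0.0774786, width: 0.0984413}
  "N": {dg0:  1.3266132, width: 0.0057172}
  "P": {dg0:  1.0860888, width: 0.0014089}
  "Q": {dg0:  1.3336109, width: 0.0125798}
  "R": {dg0:  1.6492534, width: 0.0659331}
  "S": {dg0:  0.7023921, width: 0.0019379}
  "T": {dg0:  0.5266550, width: 0.0093063}
  "V": {dg0: -0.2447218, width: 0.0979201}
  "W": {dg0:  0.2909390, width: 0.0753326, arom_dg: -0.5479140, arom_width: 0.0388691}
  "Y": {dg0:  0.6275249, width: 0.0907372, arom_dg: -0.5744404, arom_width: 0.0145576}
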