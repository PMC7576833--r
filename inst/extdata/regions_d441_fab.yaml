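# Region definitions for the anti-lysozyme D44.1 Fab crystal structures
# (PDB 1MLC antigen-bound, 1MLB free; light chain A, heavy chain B, Kabat
# numbering, Chothia CDR boundaries). Only the Fv regions are needed for
# the interface angle; constant domains and switch regions are included
# for elbow-angle work. Deposited coordinate files are not bundled.
scheme: chothia
regions:
  VL: {chain: A, ranges: [[1, 107]]}
  VH: {chain: B, ranges: [[1, 113]]}
  CL: {chain: A, ranges: [[108, 212]]}
  CH1: {chain: B, ranges: [[114, 218]]}
  CDR_L1: {chain: A, ranges: [[24, 34]]}
  CDR_L2: {chain: A, ranges: [[50, 56]]}
  CDR_L3: {chain: A, ranges: [[89, 97]]}
  CDR_H1: {chain: B, ranges: [[26, 32]]}
  CDR_H2: {chain: B, ranges: [[52, 56]]}
  CDR_H3: {chain: B, ranges: [[95, 102]]}
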