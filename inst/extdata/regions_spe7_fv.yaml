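# Region definitions for the SPE7 Fv crystal structures (PDB 1OAQ, 1OAX,
# 1OCW; light chain L, heavy chain H, Kabat numbering). CDR boundaries
# follow the Chothia definition. Deposited coordinate files are not
# bundled; place them under extdata/structures/ to run structure-level
# benchmarks.
scheme: chothia
regions:
  VL: {chain: L, ranges: [[1, 107]]}
  VH: {chain: H, ranges: [[1, 113]]}
  CDR_L1: {chain: L, ranges: [[24, 34]]}
  CDR_L2: {chain: L, ranges: [[50, 56]]}
  CDR_L3: {chain: L, ranges: [[89, 97]]}
  CDR_H1: {chain: H, ranges: [[26, 32]]}
  CDR_H2: {chain: H, ranges: [[52, 56]]}
  CDR_H3: {chain: H, ranges: [[95, 102]]}
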