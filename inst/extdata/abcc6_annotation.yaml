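# Default residue-annotation configuration for human ABCC6 (NP_001162.5).
#
# Domain and motif intervals are approximate packaged DEFAULTS assembled
# from UniProt-style annotation of the ABCC family; they are data, not
# measurements. Supply a curated configuration for production analyses.
# The membrane slab (model-frame z bounds from a membrane-placement
# computation) and ligand/ATP reference coordinates are deliberately
# unset here: they depend on the user's model frame.
domains:
  - {name: TMD0, start: 26, end: 196}
  - {name: L0, start: 197, end: 284}
  - {name: TMD1, start: 285, end: 625}
  - {name: NBD1, start: 626, end: 890}
  - {name: L1, start: 891, end: 945}
  - {name: TMD2, start: 946, end: 1254}
  - {name: NBD2, start: 1255, end: 1503}
motifs:
  - {name: walker_a, start: 691, end: 698}
  - {name: q_loop, start: 726, end: 731}
  - {name: signature, start: 785, end: 790}
  - {name: walker_b, start: 808, end: 813}
  - {name: h_loop, start: 841, end: 846}
  - {name: walker_a, start: 1297, end: 1304}
  - {name: q_loop, start: 1340, end: 1345}
  - {name: signature, start: 1400, end: 1405}
  - {name: walker_b, start: 1420, end: 1425}
  - {name: h_loop, start: 1453, end: 1458}
# Conserved regulatory phosphosites (S244 CK2 site in L0; S902 PKA site
# and the Q906 NBD1 contact in L1) plus further reported PTM positions.
ptm_sites: [244, 902, 906]
regulatory_intervals:
  - {start: 911, end: 931}
interfacial_helices:
  - {start: 204, end: 208}
  - {start: 217, end: 228}
  - {start: 931, end: 943}
# ABCC-family degenerate NBD1 stretch (conserved residues missing
# relative to other ABC proteins); approximate default.
abcc_divergent:
  - {start: 745, end: 760}
pocket_cutoff: 5
ptm_window: 3
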