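# Curated, approximate G-interface region ranges for the budding-yeast
# Cdc3-Cdc10 G dimer, in author numbering. The ranges are anchored on
# residues with described roles (Cdc3 Asp128 in G1, Asp210 in G3, Glu295 in
# the alpha-4 helix, Tyr352 in the beta meander; Cdc10 Lys155 in trans loop
# 1, Asp182 in G4, Arg251/Trp255/Ser256 in the Sep4 beta meander) and are
# meant as editable defaults, not authoritative boundaries. Sep4 and the
# beta meander are treated as one region (beta_meander).
Cdc10:
  wg: 255
  regions:
    trans_loop1: "152-158"
    G4: "180-185"
    beta_meander: "249-267"
Cdc3:
  wg: 354
  regions:
    G1: "125-133"
    G3: "207-213"
    alpha4: "290-298"
    beta_meander: "348-366"
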