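# Published array fixtures: 23 structures with printed category and rank.
atl_tab <- lectinspec::atl_glycans()

atl_structure <- function(id) atl_tab$structure[atl_tab$glycan_id == id]
atl_tree <- function(id) parse_glycan(atl_structure(id))

CORE_STRING <- "Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb"
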