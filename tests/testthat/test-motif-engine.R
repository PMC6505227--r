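test_that("core pentasaccharide query matches where it should", {
  expect_equal(count_matches(atl_tree(51), core_pentasaccharide_query()), 1)
  expect_true(has_core_pentasaccharide(atl_tree(51)))
  # core fucosylation on the reducing GlcNAc is permitted and ignored
  expect_true(has_core_pentasaccharide(atl_tree(485)))
  expect_false(has_core_pentasaccharide(parse_glycan("Mana-Sp8")))
  # a non-matching single residue gives zero matches for any query
  expect_equal(count_matches(parse_glycan("Fuca-Sp0"),
                             glycan_query("Man")), 0)
})

test_that("single-residue and wildcard queries count occurrences", {
  # oracle-computed: the 7-residue high-mannose structure holds 5 Man
  t217 <- atl_tree(217)
  q_man <- glycan_query("Man")
  expect_equal(count_matches(t217, q_man), 5)
  expect_equal(oracle_count_matches(t217, q_man), 5)
  # fully wildcarded name hits every residue
  expect_equal(count_matches(t217, glycan_query("?b1-4?")),
               oracle_count_matches(t217, glycan_query("?b1-4?")))
  expect_error(glycan_query("?"), "non-wildcard")
})

test_that("matching agrees with the brute-force all-mappings oracle", {
  queries <- list(glycan_query("Man"),
                  glycan_query("Galb1-4GlcNAc"),
                  glycan_query("?b1-4?"),
                  core_pentasaccharide_query(),
                  glycan_query("Mana1-?Man"))
  set.seed(31)
  for (k in 1:60) {
    tr <- random_tree(10)
    for (q in queries)
      expect_equal(count_matches(tr, q), oracle_count_matches(tr, q),
                   info = paste(write_glycan(tr), "|", write_glycan(q$tree)))
  }
})

test_that("adding a residue never decreases unanchored match counts", {
  q <- glycan_query("Galb1-4GlcNAc")
  set.seed(55)
  for (k in 1:50) {
    tr <- random_tree(8)
    before <- count_matches(tr, q)
    # graft one residue onto a random node at a free position
    nodes <- tr$nodes
    repeat {
      p <- sample(nodes$id, 1)
      free <- setdiff(2:6, nodes$parent_pos[!is.na(nodes$parent) &
                                              nodes$parent == p])
      if (length(free)) break
    }
    nodes <- rbind(nodes, data.frame(
      id = nrow(nodes) + 1L, name = sample(c("Gal", "GlcNAc", "Man"), 1),
      anomer = "b", anomeric_carbon = 1L, parent = p,
      parent_pos = free[1], stringsAsFactors = FALSE))
    bigger <- parse_glycan(write_glycan(structure(
      list(nodes = nodes, spacer = NA_character_, source = NA_character_),
      class = "glycan_tree")))
    expect_gte(count_matches(bigger, q), before)
  }
})

test_that("N-glycan classification reproduces the published categories", {
  expect_equal(classify_nglycan(atl_tree(217)), "high_mannose")
  expect_equal(classify_nglycan(atl_tree(389)), "complex")
  expect_equal(classify_nglycan(atl_tree(355)), "fucosylated_core")
  # core fucose with mannose-only antennae stays high-mannose
  expect_equal(classify_nglycan(atl_tree(485)), "high_mannose")
  # hybrid (one mannose arm, one substituted arm) falls to complex
  expect_equal(classify_nglycan(atl_tree(352)), "complex")
  expect_equal(classify_nglycan(parse_glycan("Mana-Sp8")), "non_core")
})

test_that("lactosamine units are counted as terminal vs internal", {
  expect_equal(lacnac_counts(atl_tree(365)), c(terminal = 1L, internal = 0L))
  expect_equal(lacnac_counts(atl_tree(51)), c(terminal = 0L, internal = 0L))
  # two arms of Galb1-4GlcNAcb1-3Galb1-4GlcNAc: one terminal + one internal each
  expect_equal(lacnac_counts(atl_tree(576)), c(terminal = 2L, internal = 2L))
})

test_that("named terminal motifs are detected only at termini", {
  expect_true(has_named_motif(atl_tree(473), "lewis_fucosylated_terminal"))
  expect_false(has_named_motif(atl_tree(51), "lewis_fucosylated_terminal"))
  expect_false(has_named_motif(atl_tree(51), "sialyl_a26_terminal"))
  expect_true(has_named_motif(parse_glycan("Neu5Aca2-6Galb1-4GlcNAcb-Sp0"),
                              "sialyl_a26_terminal"))
  # substituted sialic acid is no longer terminal
  expect_false(has_named_motif(
    parse_glycan("Galb1-4Neu5Aca2-6Galb1-4GlcNAcb-Sp0"),
    "sialyl_a26_terminal"))
  expect_error(has_named_motif(atl_tree(51), "no_such_motif"))
})

test_that("classification report covers a structure column with failures", {
  rep <- classify_report(c(1, 2, 3),
                         c(CORE_STRING, "not a glycan!", "Mana-Sp8"))
  expect_equal(rep$class, c("high_mannose", NA, "non_core"))
  expect_equal(rep$core, c(TRUE, NA, FALSE))
})
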