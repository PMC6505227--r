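#' Build a subtree motif query from a glycan string
#'
#' Queries are written in the same condensed-IUPAC dialect as structures,
#' with `?` as a wildcard for residue name, anomer, anomeric carbon or
#' attachment position: `"?b1-4GlcNAc"` matches any residue attached b1-4 to
#' a GlcNAc, `"Man?1-?"`... etc. A query must retain at least one
#' non-wildcard constraint.
#'
#' @param text Query string (CFG dialect with `?` wildcards).
#' @param anchored If `TRUE` the query root must map to the reducing-end
#'   residue of the target tree.
#' @param alphabet Residue alphabet for non-wildcard names.
#' @return A `glycan_query` (a `glycan_tree` plus `anchored` flag).
#' @export
glycan_query <- function(text, anchored = FALSE,
                         alphabet = default_monosaccharides()) {
  tree <- parse_glycan(text, alphabet = alphabet)
  nd <- tree$nodes
  constrained <- any(nd$name != "?") || any(!is.na(nd$anomer)) ||
    any(!is.na(nd$parent_pos))
  if (!constrained)
    stop("motif query has no non-wildcard constraint", call. = FALSE)
  structure(list(tree = tree, anchored = isTRUE(anchored)),
            class = "glycan_query")
}

# A query component matches leniently: a wildcard/unknown on either side
# matches anything (printed strings sometimes omit the root anomer).
.comp_ok <- function(qv, tv) is.na(qv) || is.na(tv) || qv == tv

.node_ok <- function(qn, tn, check_linkage) {
  if (qn$name != "?" && qn$name != tn$name) return(FALSE)
  if (!.comp_ok(qn$anomer, tn$anomer)) return(FALSE)
  if (check_linkage) {
    if (!.comp_ok(qn$anomeric_carbon, tn$anomeric_carbon)) return(FALSE)
    if (!.comp_ok(qn$parent_pos, tn$parent_pos)) return(FALSE)
  }
  TRUE
}

# all mappings of the query subtree rooted at qid onto the target subtree
# rooted at tid; returns list of named integer vectors (query id -> tree id)
.match_at <- function(qtree, tqnodes, ttree, qid, tid, check_linkage) {
  if (!.node_ok(tqnodes[qid, ], ttree$nodes[tid, ], check_linkage))
    return(list())
  qkids <- which(!is.na(tqnodes$parent) & tqnodes$parent == qid)
  base <- list(setNames(tid, qid))
  if (!length(qkids)) return(base)
  tkids <- .children(ttree, tid)
  if (length(tkids) < length(qkids)) return(list())

  assign_kids <- function(qs, avail) {
    if (!length(qs)) return(list(integer(0)))
    out <- list()
    q1 <- qs[1]
    for (t1 in avail) {
      subs <- .match_at(qtree, tqnodes, ttree, q1, t1, TRUE)
      if (!length(subs)) next
      tails <- assign_kids(qs[-1], setdiff(avail, t1))
      for (s in subs) for (tl in tails)
        out[[length(out) + 1L]] <- c(s, tl)
    }
    out
  }
  combos <- assign_kids(qkids, tkids)
  unlist(lapply(combos, function(cmb) lapply(base, function(b) c(b, cmb))),
         recursive = FALSE)
}

#' Find all subtree matches of a motif query in a glycan tree
#'
#' A match maps every query node to a distinct tree node, preserving
#' parent/child edges and attachment positions (unless wildcarded) and
#' satisfying name/anomer constraints; the target may carry extra residues
#' anywhere. Anchored queries map the query root to the reducing-end residue.
#' All matches are reported.
#'
#' @param tree A `glycan_tree`.
#' @param query A `glycan_query` (or a query string, parsed unanchored).
#' @return List of matches; each is a named integer vector sending query node
#'   ids (names) to tree node ids.
#' @export
match_subtree <- function(tree, query) {
  .check_tree(tree)
  if (is.character(query)) query <- glycan_query(query)
  stopifnot(inherits(query, "glycan_query"))
  q <- query$tree
  qroot <- .root_id(q)
  starts <- if (query$anchored) .root_id(tree) else tree$nodes$id
  out <- list()
  for (tid in starts) {
    # the query root's own linkage is unconstrained (it may sit anywhere)
    m <- .match_at(q, q$nodes, tree, qroot, tid, FALSE)
    out <- c(out, m)
  }
  out
}

#' Count subtree matches
#' @inheritParams match_subtree
#' @return Integer number of distinct match mappings.
#' @export
count_matches <- function(tree, query) length(match_subtree(tree, query))

#' The N-glycan core pentasaccharide as a motif query
#'
#' The trimannosyl core Man a1-6 (Man a1-3) Man b1-4 GlcNAc b1-4 GlcNAc,
#' anchored at the reducing end.
#' @return An anchored `glycan_query`.
#' @export
core_pentasaccharide_query <- function() {
  glycan_query("Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb", anchored = TRUE)
}

#' Does a glycan carry the N-glycan core pentasaccharide?
#'
#' `TRUE` iff the anchored trimannosyl core matches at the reducing end; an
#' additional Fuc a1-6 on the reducing GlcNAc (core fucosylation) is
#' permitted and ignored.
#'
#' @param tree A `glycan_tree`.
#' @return `TRUE` or `FALSE`.
#' @export
has_core_pentasaccharide <- function(tree) {
  count_matches(tree, core_pentasaccharide_query()) > 0L
}

# node ids of the (unique) core mapping, or NULL
.core_ids <- function(tree) {
  m <- match_subtree(tree, core_pentasaccharide_query())
  if (!length(m)) return(NULL)
  unname(m[[1]])
}

# id of a Fuc attached a1-6 to the reducing-end GlcNAc, or integer(0)
.core_fucose <- function(tree) {
  root <- .root_id(tree)
  kids <- .children(tree, root)
  nd <- tree$nodes[kids, , drop = FALSE]
  kids[nd$name == "Fuc" & !is.na(nd$parent_pos) & nd$parent_pos == 6 &
         (is.na(nd$anomer) | nd$anomer == "a")]
}

#' Classify an N-glycan into array-style categories
#'
#' Categories mirror the standard grouping of N-glycans on a mammalian glycan
#' array: `non_core` if the trimannosyl core pentasaccharide is absent;
#' otherwise `fucosylated_core` if the reducing GlcNAc carries Fuc a1-6 and
#' any antennary residue beyond the core is non-mannose; otherwise
#' `high_mannose` if every residue beyond the core (ignoring the core fucose)
#' is mannose; otherwise `complex`. Hybrid structures (one mannose arm, one
#' substituted arm) therefore fall to `complex`, and a core-fucosylated
#' glycan with mannose-only antennae remains `high_mannose`.
#'
#' @param tree A `glycan_tree`.
#' @return One of `"high_mannose"`, `"complex"`, `"fucosylated_core"`,
#'   `"non_core"`.
#' @export
classify_nglycan <- function(tree) {
  core <- .core_ids(tree)
  if (is.null(core)) return("non_core")
  fuc <- .core_fucose(tree)
  antennary <- setdiff(tree$nodes$id, c(core, fuc))
  non_man <- any(tree$nodes$name[antennary] != "Man")
  if (length(fuc) && non_man) return("fucosylated_core")
  if (!non_man) return("high_mannose")
  "complex"
}

#' Terminal and internal lactosamine counts
#'
#' Counts Gal b1-4 GlcNAc (LacNAc) units: terminal when the Gal is a leaf,
#' internal when the Gal is further substituted. Each GlcNAc anchors at most
#' one counted unit.
#'
#' @param tree A `glycan_tree`.
#' @return Named integer vector `c(terminal = , internal = )`.
#' @export
lacnac_counts <- function(tree) {
  .check_tree(tree)
  nd <- tree$nodes
  gal <- which(nd$name == "Gal" & !is.na(nd$parent) &
                 (is.na(nd$anomer) | nd$anomer == "b") &
                 !is.na(nd$parent_pos) & nd$parent_pos == 4 &
                 nd$name[nd$parent] == "GlcNAc")
  gal <- gal[!duplicated(nd$parent[gal])]
  leaf <- vapply(gal, function(g) length(.children(tree, g)) == 0L, logical(1))
  c(terminal = sum(leaf), internal = sum(!leaf))
}

# every query leaf must land on a tree leaf (non-reducing terminus)
.terminal_match <- function(tree, qtree, mapping) {
  qleaves <- setdiff(qtree$nodes$id, qtree$nodes$parent)
  all(vapply(qleaves, function(q) {
    length(.children(tree, mapping[[as.character(q)]])) == 0L
  }, logical(1)))
}

#' Test for named terminal motifs
#'
#' `lewis_fucosylated_terminal` is the difucosylated terminal unit
#' Fuc a1-2 Gal b1-4 (Fuc a1-3) GlcNAc exactly as printed on the array;
#' `sialyl_a26_terminal` is the influenza-receptor terminal sequence
#' Neu5Ac a2-6 Gal b1-4 -. Both must occur at a non-reducing terminus (the
#' motif's outermost residues are unsubstituted).
#'
#' @param tree A `glycan_tree`.
#' @param name One of `"lewis_fucosylated_terminal"`, `"sialyl_a26_terminal"`.
#' @return `TRUE` or `FALSE`.
#' @export
has_named_motif <- function(tree,
                            name = c("lewis_fucosylated_terminal",
                                     "sialyl_a26_terminal")) {
  name <- match.arg(name)
  qtext <- switch(name,
                  lewis_fucosylated_terminal = "Fuca1-2Galb1-4(Fuca1-3)GlcNAcb",
                  sialyl_a26_terminal = "Neu5Aca2-6Galb1-4?")
  q <- glycan_query(qtext)
  maps <- match_subtree(tree, q)
  any(vapply(maps, function(m) .terminal_match(tree, q$tree, m), logical(1)))
}

#' Classification report for a set of structures
#'
#' Parses and classifies a vector of glycan strings; unparseable rows are
#' reported as `NA` class.
#'
#' @param glycan_id Identifiers.
#' @param structure Glycan strings.
#' @return Tibble with `glycan_id`, `structure`, `class`, `core`,
#'   `core_fucose`, `terminal_lacnac`, `internal_lacnac`.
#' @export
classify_report <- function(glycan_id, structure) {
  parsed <- parse_glycans(structure)
  rows <- lapply(seq_along(structure), function(i) {
    tr <- parsed$trees[[i]]
    if (is.null(tr)) {
      return(tibble::tibble(glycan_id = glycan_id[i], structure = structure[i],
                            class = NA_character_, core = NA, core_fucose = NA,
                            terminal_lacnac = NA_integer_,
                            internal_lacnac = NA_integer_))
    }
    ln <- lacnac_counts(tr)
    tibble::tibble(glycan_id = glycan_id[i], structure = structure[i],
                   class = classify_nglycan(tr),
                   core = has_core_pentasaccharide(tr),
                   core_fucose = length(.core_fucose(tr)) > 0L,
                   terminal_lacnac = ln[["terminal"]],
                   internal_lacnac = ln[["internal"]])
  })
  dplyr::bind_rows(rows)
}
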