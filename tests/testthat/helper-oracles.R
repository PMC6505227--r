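# Brute-force all-mappings oracle for subtree matching: exhaustive DFS over
# injective partial mappings of query nodes (in id order) onto tree nodes,
# checking every constraint directly on the node tables. Independent of the
# package's structural recursion.
oracle_count_matches <- function(tree, query) {
  q <- query$tree$nodes
  t <- tree$nodes
  lenient <- function(a, b) is.na(a) || is.na(b) || a == b
  node_ok <- function(qi, ti, is_qroot) {
    if (q$name[qi] != "?" && q$name[qi] != t$name[ti]) return(FALSE)
    if (!lenient(q$anomer[qi], t$anomer[ti])) return(FALSE)
    if (!is_qroot) {
      if (!lenient(q$anomeric_carbon[qi], t$anomeric_carbon[ti])) return(FALSE)
      if (!lenient(q$parent_pos[qi], t$parent_pos[ti])) return(FALSE)
    }
    TRUE
  }
  qroot <- q$id[is.na(q$parent)]
  troot <- t$id[is.na(t$parent)]
  # assign query nodes in an order where parents come first
  ord <- qroot
  while (length(ord) < nrow(q))
    ord <- c(ord, q$id[!q$id %in% ord & q$parent %in% ord])
  n_found <- 0L
  recurse <- function(k, map) {
    if (k > length(ord)) {
      n_found <<- n_found + 1L
      return(invisible(NULL))
    }
    qi <- ord[k]
    cands <- if (qi == qroot && query$anchored) troot else t$id
    for (ti in setdiff(cands, map)) {
      if (!node_ok(qi, ti, qi == qroot)) next
      if (qi != qroot) {
        # edge preservation, checked on the candidate pair itself
        if (is.na(t$parent[ti]) || t$parent[ti] != map[q$parent[qi]]) next
      }
      map2 <- map
      map2[qi] <- ti
      recurse(k + 1L, map2)
    }
    invisible(NULL)
  }
  recurse(1L, rep(NA_integer_, nrow(q)))
  n_found
}

# random glycan tree of at most max_nodes residues, via the library generator
random_tree <- function(max_nodes = 10L) {
  lib <- gen_glycan_library(1, max_residues = max_nodes)
  parse_glycan(lib$glycans$structure[1])
}
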