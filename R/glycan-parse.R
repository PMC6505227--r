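#' @importFrom rlang .data
#' @importFrom stats median sd setNames rnorm rlnorm runif coef vcov optimize fitted residuals
#' @importFrom utils head tail
NULL

#' Default monosaccharide alphabet
#'
#' Symbols covering the monosaccharides that occur in CFG mammalian glycan
#' array (v5.0) structure strings, in the condensed-IUPAC dialect used on the
#' printed arrays (e.g. `Man`, `GlcNAc`, `Neu5Ac`). The alphabet is
#' configurable in [parse_glycan()]; ordering is irrelevant (the tokenizer
#' always takes the longest match).
#'
#' @return Character vector of residue symbols.
#' @export
default_monosaccharides <- function() {
  c("GlcNAc", "GalNAc", "ManNAc", "Neu5Ac", "Neu5Gc", "Neu5,9Ac2",
    "GlcA", "IdoA", "GalA", "ManA", "MurNAc",
    "Man", "Gal", "Glc", "Fuc", "Xyl", "Rha", "Ara", "Rib", "Kdn", "KDN",
    "Abe", "Api", "Fru", "Qui")
}

# Longest-first alternation so "GlcNAc" wins over "Glc".
.alphabet_regex <- function(alphabet) {
  alphabet <- alphabet[order(-nchar(alphabet))]
  paste0("^(", paste(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", alphabet),
                     collapse = "|"), ")")
}

.parse_error <- function(text, offset, msg) {
  stop(sprintf("glycan parse error at offset %d ('%s'): %s",
               offset, substr(text, offset, min(nchar(text), offset + 9)), msg),
       call. = FALSE)
}

#' Parse a condensed-IUPAC (CFG dialect) glycan string
#'
#' Reads structure strings such as
#' `"Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb-Sp13"` into a rooted tree of
#' monosaccharide residues. The rightmost residue before the spacer is the
#' root (reducing end); a parenthesized group attaches as a branch to the
#' first residue to its right at the same nesting depth; a linkage token like
#' `a1-6` carries the child's anomeric configuration (`a`), anomeric carbon
#' (`1`) and attachment position on the parent (`6`). A trailing `-SpN` tag
#' names the spacer arm and is preserved but never counted as a residue.
#' Roots printed without an anomer (e.g. `...GlcNAc-Sp21`) parse with
#' `anomer = NA`. A `?` is accepted for any residue name, anomer, anomeric
#' carbon or position (used by motif queries; see [glycan_query()]).
#'
#' @param text A single glycan string. Internal whitespace is ignored.
#' @param alphabet Permitted residue symbols.
#' @return A `glycan_tree`: list with `nodes` (data frame with columns `id`,
#'   `name`, `anomer`, `anomeric_carbon`, `parent`, `parent_pos`; root has
#'   `parent = NA`), `spacer` (or `NA`) and `source` (the input string).
#' @examples
#' tr <- parse_glycan("Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAcb-Sp13")
#' nrow(tr$nodes)            # 5 residues
#' glycan_composition(tr)    # Man x3, GlcNAc x2
#' @export
parse_glycan <- function(text, alphabet = default_monosaccharides()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  orig <- text
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("glycan parse error: empty string", call. = FALSE)

  spacer <- NA_character_
  sp <- regmatches(s, regexpr("-Sp[0-9]+$", s))
  if (length(sp)) {
    spacer <- sub("^-", "", sp)
    s <- sub("-Sp[0-9]+$", "", s)
  }
  if (!nzchar(s)) .parse_error(orig, 1L, "no residues before spacer")

  res_re <- .alphabet_regex(c(alphabet, "?"))
  n_open <- 0L

  name <- character(); anomer <- character(); acarb <- character()
  parent <- integer(); ppos <- character()
  # one pending list per nesting depth: children awaiting the next residue
  # to their right (id + attachment position on that future parent)
  pending <- list(list())
  root <- NA_integer_
  p <- 1L
  nch <- nchar(s)

  new_node <- function(nm, an, ac) {
    name[length(name) + 1L] <<- nm
    anomer[length(anomer) + 1L] <<- an
    acarb[length(acarb) + 1L] <<- ac
    parent[length(parent) + 1L] <<- NA_integer_
    ppos[length(ppos) + 1L] <<- NA_character_
    length(name)
  }

  while (p <= nch) {
    ch <- substr(s, p, p)
    if (ch == "(") {
      n_open <- n_open + 1L
      pending[[length(pending) + 1L]] <- list()
      p <- p + 1L
    } else if (ch == ")") {
      if (n_open == 0L) .parse_error(orig, p, "unbalanced ')'")
      if (length(pending[[length(pending)]]) == 0L)
        .parse_error(orig, p, "empty branch")
      d <- length(pending)
      pending[[d - 1L]] <- c(pending[[d - 1L]], pending[[d]])
      pending[[d]] <- NULL
      n_open <- n_open - 1L
      p <- p + 1L
    } else {
      m <- regexpr(res_re, substr(s, p, nch), perl = TRUE)
      if (m == -1L) .parse_error(orig, p, "unknown residue symbol")
      len <- attr(m, "match.length")
      nm <- substr(s, p, p + len - 1L)
      p <- p + len
      rest <- substr(s, p, nch)
      lk <- regmatches(rest, regexpr("^[ab?][12?]-[2-9?]", rest))
      if (length(lk)) {
        an <- substr(lk, 1, 1); ac <- substr(lk, 2, 2); pos <- substr(lk, 4, 4)
        id <- new_node(nm, an, ac)
        for (child in pending[[length(pending)]]) {
          parent[child$id] <- id
          ppos[child$id] <- child$pos
        }
        pending[[length(pending)]] <- list(list(id = id, pos = pos))
        p <- p + nchar(lk)
      } else {
        # root residue: optional bare anomer, then end of string at depth 0
        an <- NA_character_
        if (p <= nch && substr(s, p, p) %in% c("a", "b", "?")) {
          an <- substr(s, p, p)
          p <- p + 1L
        }
        if (n_open > 0L)
          .parse_error(orig, p, "residue without linkage inside a branch")
        if (p <= nch)
          .parse_error(orig, p, "malformed linkage or trailing text")
        id <- new_node(nm, an, NA_character_)
        for (child in pending[[1L]]) {
          parent[child$id] <- id
          ppos[child$id] <- child$pos
        }
        pending[[1L]] <- list()
        root <- id
      }
    }
  }
  if (n_open > 0L) .parse_error(orig, nch, "unbalanced '(' (missing ')')")
  if (is.na(root)) .parse_error(orig, nch, "string ends with a linkage (no reducing-end residue)")

  to_int <- function(x) ifelse(x == "?" | is.na(x), NA_integer_,
                               suppressWarnings(as.integer(x)))
  nodes <- data.frame(
    id = seq_along(name),
    name = name,
    anomer = ifelse(anomer == "?", NA_character_, anomer),
    anomeric_carbon = to_int(acarb),
    parent = parent,
    parent_pos = to_int(ppos),
    stringsAsFactors = FALSE
  )
  dup <- !is.na(nodes$parent) & !is.na(nodes$parent_pos) &
    duplicated(paste(nodes$parent, nodes$parent_pos))
  if (any(dup))
    .parse_error(orig, 1L, sprintf(
      "two residues attached at position %d of the same parent",
      nodes$parent_pos[which(dup)[1]]))

  structure(list(nodes = nodes, spacer = spacer, source = orig),
            class = "glycan_tree")
}

.check_tree <- function(tree) {
  if (!inherits(tree, "glycan_tree")) stop("not a glycan_tree", call. = FALSE)
  invisible(tree)
}

.children <- function(tree, id) which(!is.na(tree$nodes$parent) &
                                        tree$nodes$parent == id)

.root_id <- function(tree) which(is.na(tree$nodes$parent))

# canonical child order: descending attachment position (NA last),
# then lexicographic on the serialized subtree so output is deterministic
.ordered_children <- function(tree, id) {
  kids <- .children(tree, id)
  if (length(kids) < 2L) return(kids)
  pos <- tree$nodes$parent_pos[kids]
  sub <- vapply(kids, function(k) .serialize(tree, k), character(1))
  kids[order(-ifelse(is.na(pos), -Inf, pos), sub)]
}

.linkage_text <- function(tree, id) {
  nd <- tree$nodes[id, ]
  paste0(ifelse(is.na(nd$anomer), "?", nd$anomer),
         ifelse(is.na(nd$anomeric_carbon), "?", nd$anomeric_carbon),
         "-",
         ifelse(is.na(nd$parent_pos), "?", nd$parent_pos))
}

.serialize <- function(tree, id) {
  kids <- .ordered_children(tree, id)
  out <- ""
  if (length(kids)) {
    first <- kids[1L]
    out <- paste0(.serialize(tree, first), .linkage_text(tree, first))
    for (k in kids[-1L])
      out <- paste0(out, "(", .serialize(tree, k), .linkage_text(tree, k), ")")
  }
  paste0(out, tree$nodes$name[id])
}

#' Serialize a glycan tree back to its condensed-IUPAC string
#'
#' Inverse of [parse_glycan()]: `parse_glycan(write_glycan(t))` is
#' structurally identical to `t`. Branch ordering in the output is canonical
#' (descending attachment position on each parent), so two structurally
#' identical trees always serialize to the same string.
#'
#' @param tree A `glycan_tree`.
#' @param spacer Include the spacer tag, if any.
#' @return A glycan string.
#' @export
write_glycan <- function(tree, spacer = TRUE) {
  .check_tree(tree)
  root <- .root_id(tree)
  out <- .serialize(tree, root)
  an <- tree$nodes$anomer[root]
  if (!is.na(an)) out <- paste0(out, an)
  if (spacer && !is.na(tree$spacer)) out <- paste0(out, "-", tree$spacer)
  out
}

#' Monosaccharide composition of a glycan tree
#'
#' @param tree A `glycan_tree`.
#' @return Named integer vector of residue counts (alphabetical by symbol);
#'   the counts sum to the number of residues in the tree.
#' @export
glycan_composition <- function(tree) {
  .check_tree(tree)
  tab <- table(tree$nodes$name)
  setNames(as.integer(tab), names(tab))
}

#' Number of residues in a glycan tree
#' @param tree A `glycan_tree`.
#' @return Integer residue count (spacer tags never count).
#' @export
n_residues <- function(tree) {
  .check_tree(tree)
  nrow(tree$nodes)
}

#' Structural identity of two glycan trees
#'
#' Compares node sets and edges (residue names, anomers, anomeric carbons and
#' attachment positions) via canonical serialization; the original source
#' text and, optionally, the spacer tag are ignored.
#'
#' @param a,b `glycan_tree` objects.
#' @param spacer Also require identical spacer tags.
#' @return `TRUE` or `FALSE`.
#' @export
glycan_identical <- function(a, b, spacer = FALSE) {
  write_glycan(a, spacer = spacer) == write_glycan(b, spacer = spacer)
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat(sprintf("<glycan_tree> %d residues%s\n  %s\n", nrow(x$nodes),
              if (!is.na(x$spacer)) paste0(", spacer ", x$spacer) else "",
              write_glycan(x)))
  invisible(x)
}

#' Parse a column of glycan strings
#'
#' Vectorized wrapper around [parse_glycan()] for array tables; parse
#' failures are collected rather than thrown.
#'
#' @param texts Character vector of glycan strings.
#' @param alphabet Permitted residue symbols.
#' @return List with `trees` (list, `NULL` where parsing failed) and
#'   `errors` (tibble of line numbers and messages).
#' @export
parse_glycans <- function(texts, alphabet = default_monosaccharides()) {
  trees <- vector("list", length(texts))
  errs <- list()
  for (i in seq_along(texts)) {
    t <- tryCatch(parse_glycan(texts[i], alphabet), error = function(e) e)
    if (inherits(t, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(line = i,
                                                  message = conditionMessage(t))
    } else trees[[i]] <- t
  }
  list(trees = trees,
       errors = if (length(errs)) dplyr::bind_rows(errs)
                else tibble::tibble(line = integer(), message = character()))
}
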