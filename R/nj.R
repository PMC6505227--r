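.aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- alignment
  } else {
    if (!is.character(alignment) || is.null(names(alignment)))
      stop("alignment must be a named character vector (or character matrix)",
           call. = FALSE)
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("alignment rows have unequal lengths (sequences not aligned)",
           call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  if (nrow(m) < 2) stop("need at least 2 taxa", call. = FALSE)
  m
}

#' Number-of-differences distance with complete deletion
#'
#' Every alignment column containing a gap (`-`) or missing symbol (`?`) in
#' any row is removed first (complete deletion); the distance between two
#' taxa is then the raw count of remaining columns at which they differ —
#' amino-acid differences per sequence, not normalized per site.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (or a character matrix, taxa in rows).
#' @return Symmetric numeric matrix with zero diagonal and taxa dimnames.
#' @export
diff_distance <- function(alignment) {
  m <- .aln_matrix(alignment)
  keep <- colSums(m == "-" | m == "?") == 0
  if (!any(keep))
    stop("complete deletion removed every column", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Standard NJ agglomeration: at each step the pair minimizing the
#' Q-criterion \eqn{Q_{ij} = (m-2) d_{ij} - r_i - r_j} is joined, branch
#' lengths are assigned from the rate-corrected split and the matrix is
#' reduced, until three nodes remain and are joined in an unrooted
#' trifurcation. Ties in Q are broken deterministically by the lowest
#' (i, j) pair in the current taxon ordering. Negative branch lengths are
#' retained (not clamped) and flagged, so that trees are recovered exactly
#' from additive matrices.
#'
#' @param d Symmetric distance matrix with taxa dimnames (e.g. from
#'   [diff_distance()]).
#' @return An [ape::ape-package] `phylo` (unrooted), with attribute
#'   `negative_branches` (`TRUE` if any branch length is negative).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 0))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("nonzero diagonal", call. = FALSE)
  m <- nrow(d)
  if (m < 3) stop("need at least 3 taxa", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(m))
  # each active node carries a newick fragment
  nwk <- labs

  fmt <- function(x) formatC(x, digits = 17, format = "g")
  while (m > 3) {
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    best <- c(NA_integer_, NA_integer_); qbest <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] < qbest) { qbest <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dk; d[, i] <- dk; d[i, i] <- 0
    nwk[i] <- new_nwk
    keep <- setdiff(seq_len(m), j)
    d <- d[keep, keep, drop = FALSE]
    nwk <- nwk[keep]
    m <- m - 1
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", nwk[1], ":", fmt(l1), ",", nwk[2], ":", fmt(l2), ",",
                nwk[3], ":", fmt(l3), ");")
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branches") <- any(tree$edge.length < 0)
  tree
}

# leaf-label set below each edge (child side), as a list parallel to edges
.edge_leafsets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(k) sort(desc[[tree$edge[k, 2]]]))
}

#' Is a set of taxa monophyletic on an unrooted tree?
#'
#' `TRUE` iff removing some single edge separates exactly the given taxa
#' from the rest (equivalently, the subset or its complement is a
#' bipartition of the tree).
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels.
#' @return `TRUE` or `FALSE`.
#' @export
monophyly_check <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(taxa %in% tips))
    stop("unknown taxa: ", paste(setdiff(taxa, tips), collapse = ", "),
         call. = FALSE)
  taxa <- sort(unique(taxa))
  if (length(taxa) %in% c(1L, length(tips))) return(TRUE)
  comp <- sort(setdiff(tips, taxa))
  for (ls in .edge_leafsets(tree)) {
    if (identical(ls, taxa) || identical(ls, comp)) return(TRUE)
  }
  FALSE
}

#' Unordered bipartition set of an unrooted tree
#'
#' Each internal edge contributes the (lexicographically smaller side of
#' the) split it induces; two trees have the same unrooted topology iff
#' their bipartition sets are equal. Used for topology comparison instead of
#' newick text, which depends on rotation and root placement.
#'
#' @param tree A `phylo` tree.
#' @return A character vector, one `|`-joined split side per internal edge,
#'   sorted.
#' @export
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  sets <- .edge_leafsets(tree)
  internal <- vapply(sets, function(s) length(s) > 1 && length(s) < n - 1,
                     logical(1))
  # canonical side: the one not containing the first tip label
  out <- vapply(sets[internal], function(s) {
    side <- if (tips[1] %in% s) sort(setdiff(tips, s)) else s
    paste(side, collapse = "|")
  }, character(1))
  sort(unique(out))
}
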