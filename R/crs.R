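# Average residue masses (Da) of the 20 standard amino acids; a peptide's
# average mass is the sum of residue masses plus one water (18.0153 Da).
.aa_residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.water_mass <- 18.0153

.seq_string <- function(seq) {
  if (is.list(seq) && !is.null(seq$sequence)) seq <- seq$sequence
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

#' Default hydrophobic residue set
#'
#' Residues accepted at the hydrophobic (`Z`) positions of the extended
#' carbohydrate-recognition-site consensus; configurable in
#' [scan_extended()].
#' @return Character vector of one-letter codes.
#' @export
default_hydrophobic <- function() c("A", "V", "L", "I", "M", "F", "W", "C", "Y")

.overlap_scan <- function(s, pattern) {
  m <- gregexpr(paste0("(?=(", pattern, "))"), s, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble::tibble(start = integer(), end = integer(),
                                        match = character()))
  starts <- as.integer(attr(m, "capture.start")[, 1])
  lens <- as.integer(attr(m, "capture.length")[, 1])
  tibble::tibble(start = starts, end = starts + lens - 1L,
                 match = substring(s, starts, starts + lens - 1L))
}

#' Scan a protein for the CRS core consensus \[QXDXNXVXY\]
#'
#' Reports every (possibly overlapping) 9-mer with Q, D, N, V, Y fixed at
#' positions 1, 3, 5, 7 and 9 and any residue at the X positions — the
#' mannose-binding carbohydrate-recognition-site consensus of GNA-related
#' (bulb-type, beta-prism II) lectins. Coordinates are 1-based inclusive.
#'
#' @param seq One-letter protein sequence (character scalar, or a list with a
#'   `sequence` element).
#' @return Tibble with `start`, `end`, `match`, `extended = FALSE`.
#' @export
scan_crs <- function(seq) {
  s <- .seq_string(seq)
  if (nchar(s) < 9) stop("sequence shorter than the 9-mer consensus",
                         call. = FALSE)
  out <- .overlap_scan(s, "Q[A-Z]D[A-Z]N[A-Z]V[A-Z]Y")
  out$extended <- rep(FALSE, nrow(out))
  out
}

#' Scan for the extended CRS consensus \[ZQXDXNZVZY\]
#'
#' The 10-mer extension of the core consensus: position 1 is restricted to
#' M/I/L/V, positions 2,4,6,8,10 are Q,D,N,V,Y, positions 7 and 9 come from
#' the hydrophobic set (together with the fixed V they form the hydrophobic
#' triplet implicated in van der Waals contacts with mannose) and positions
#' 3,5 are free. Every extended match contains a core match at offset +1.
#'
#' @param seq Protein sequence as in [scan_crs()].
#' @param hydrophobic Residues permitted at the non-leading `Z` positions.
#' @return Tibble with `start`, `end`, `match`, `extended = TRUE`,
#'   `core_start` (start of the embedded 9-mer) and `triplet` (positions
#'   7-9 of the match).
#' @export
scan_extended <- function(seq, hydrophobic = default_hydrophobic()) {
  s <- .seq_string(seq)
  if (nchar(s) < 10) stop("sequence shorter than the 10-mer consensus",
                          call. = FALSE)
  hyd <- paste0("[", paste(hydrophobic, collapse = ""), "]")
  out <- .overlap_scan(s, paste0("[MILV]Q[A-Z]D[A-Z]N", hyd, "V", hyd, "Y"))
  out$extended <- rep(TRUE, nrow(out))
  out$core_start <- out$start + 1L
  out$triplet <- substring(out$match, 7, 9)
  out
}

#' Define domain spans on a protein
#'
#' @param name Domain names.
#' @param start,end 1-based inclusive coordinates.
#' @return Tibble of domain spans (overlaps allowed).
#' @export
domain_spans <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end),
            all(start >= 1), all(end >= start))
  tibble::tibble(name = as.character(name), start = as.integer(start),
                 end = as.integer(end))
}

#' Count CRS matches per domain
#'
#' A match counts for a domain iff it is fully contained in the domain's
#' span; matches straddling a boundary count for neither side.
#'
#' @param seq Protein sequence.
#' @param domains A [domain_spans()] tibble.
#' @param matches Optional precomputed match tibble; defaults to
#'   [scan_crs()] on `seq`.
#' @return Named integer vector of per-domain counts.
#' @export
crs_per_domain <- function(seq, domains, matches = NULL) {
  s <- .seq_string(seq)
  if (nrow(domains) && any(domains$end > nchar(s)))
    stop("domain span extends beyond sequence end", call. = FALSE)
  if (is.null(matches)) matches <- scan_crs(s)
  counts <- vapply(seq_len(nrow(domains)), function(i) {
    sum(matches$start >= domains$start[i] & matches$end <= domains$end[i])
  }, integer(1))
  setNames(counts, domains$name)
}

#' Residue downstream of a CRS match and its mannose-binding flag
#'
#' In mannose-binding bulb lectins an alanine sits just downstream of the
#' conserved CRS; its substitution by glutamine is diagnostic of lost
#' mannose specificity. Returns the residue at `end + offset` of each match
#' and flags it `"mannose-type"` (A), `"substituted"` (Q) or `"other"`.
#'
#' @param seq Protein sequence.
#' @param matches Match tibble from [scan_crs()] or [scan_extended()].
#' @param offset Residues past the match end (default 1).
#' @return `matches` with added columns `downstream` and `flag`.
#' @export
downstream_flag <- function(seq, matches, offset = 1L) {
  s <- .seq_string(seq)
  pos <- matches$end + offset
  if (any(pos > nchar(s)))
    stop("downstream offset falls beyond the sequence end", call. = FALSE)
  res <- substring(s, pos, pos)
  matches$downstream <- res
  matches$flag <- ifelse(res == "A", "mannose-type",
                         ifelse(res == "Q", "substituted", "other"))
  matches
}

#' Basic sequence-derived properties
#'
#' For proteins: length and predicted average molecular mass (sum of
#' standard average residue masses plus one water; `X` residues make the
#' mass `NA`). For nucleotides: length and GC percentage reported to one
#' decimal.
#'
#' @param seq Sequence string (or list with `sequence`).
#' @param type `"protein"`, `"nucleotide"`, or `"auto"` (nucleotide iff all
#'   characters are in ACGTUN).
#' @return List with `type`, `length`, and `mass_da` (protein) or
#'   `gc_percent` (nucleotide).
#' @export
seq_properties <- function(seq, type = c("auto", "protein", "nucleotide")) {
  s <- .seq_string(seq)
  type <- match.arg(type)
  chars <- strsplit(s, "")[[1]]
  if (type == "auto")
    type <- if (all(chars %in% c("A", "C", "G", "T", "U", "N")))
      "nucleotide" else "protein"
  if (type == "nucleotide") {
    if (!all(chars %in% c("A", "C", "G", "T", "U", "N")))
      stop("invalid nucleotide alphabet", call. = FALSE)
    gc <- round(100 * sum(chars %in% c("G", "C")) / length(chars), 1)
    list(type = "nucleotide", length = length(chars), gc_percent = gc)
  } else {
    ok <- chars %in% c(names(.aa_residue_mass), "X")
    if (!all(ok))
      stop("invalid protein alphabet: ", paste(unique(chars[!ok]),
                                               collapse = ""), call. = FALSE)
    mass <- if (any(chars == "X")) NA_real_
            else sum(.aa_residue_mass[chars]) + .water_mass
    list(type = "protein", length = length(chars), mass_da = mass)
  }
}
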