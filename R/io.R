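#' Read a glycan-array CSV
#'
#' Expects columns `glycan_id`, `structure` (optional), `concentration` and
#' replicate columns `rep1..repK`; returns the long form used by
#' [rank_table()].
#'
#' @param path CSV path.
#' @return Long tibble with `glycan_id`, `structure`, `concentration`,
#'   `replicate`, `rfu`.
#' @export
read_array_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  reps <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (!length(reps) || !all(c("glycan_id", "concentration") %in% names(df)))
    stop("malformed array CSV: need glycan_id, concentration, rep1..repK",
         call. = FALSE)
  tidyr::pivot_longer(df, dplyr::all_of(reps), names_to = "replicate",
                      names_prefix = "rep", values_to = "rfu") |>
    dplyr::mutate(replicate = as.integer(.data$replicate))
}

#' Write a glycan-array dataset as the wide CSV dialect
#'
#' Inverse of [read_array_csv()].
#'
#' @param dataset Long tibble (`glycan_id`, `concentration`, `replicate`,
#'   `rfu`, optional `structure`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_array_csv <- function(dataset, path) {
  wide <- dataset |>
    dplyr::mutate(replicate = paste0("rep", .data$replicate)) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "rfu")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Write a rank table as CSV
#' @param table A [rank_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_csv <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Write binder partitions as JSON
#'
#' @param partition Named list (per concentration) of lists with `binders`
#'   and `non_binders`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  slim <- lapply(partition, function(p) p[c("binders", "non_binders")])
  jsonlite::write_json(slim, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Minimal FASTA reader (first whitespace-delimited word of the header is
#' the id); sequences may span multiple lines.
#'
#' @param path FASTA path.
#' @param aligned If `TRUE`, require equal lengths (an alignment).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path, call. = FALSE)
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("[[:space:]]", "", paste(x, collapse = "")),
                 character(1))
  out <- setNames(unname(seqs), ids)
  if (aligned && length(unique(nchar(out))) != 1L)
    stop("sequences have unequal lengths (not an alignment): ", path,
         call. = FALSE)
  out
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(nchar(s), seq(1, nchar(s), width) + width - 1)),
               con)
  }
  invisible(path)
}
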