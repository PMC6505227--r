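#' Bundled glycan-array specificity table for the A. tortuosum lectin
#'
#' The 23 highest-binding structures from the published CFG mammalian glycan
#' array (v5.0) screen of the Arisaema tortuosum lectin (deposited as CFG
#' request cfg_rRequest_2313), with their printed N-glycan category and
#' average rank over the three lectin concentrations (10, 1 and 0.1 ug/ml).
#'
#' @return Tibble with `glycan_id`, `structure`, `class`, `avg_rank`.
#' @export
atl_glycans <- function() {
  path <- system.file("extdata", "atl_cfg_array_v5_ranks.csv",
                      package = "lectinspec", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    glycan_id = readr::col_integer(),
                    structure = readr::col_character(),
                    class = readr::col_character(),
                    avg_rank = readr::col_double()))
}

.write_run_log <- function(output_dir, config) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- c(config,
           list(package = "lectinspec",
                version = as.character(utils::packageVersion("lectinspec")),
                r_version = R.version.string))
  jsonlite::write_json(cfg, file.path(output_dir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(NULL)
}

#' Run the full glycan-array analysis pipeline
#'
#' Replicate summarization, per-concentration percent-of-max normalization,
#' rank averaging, threshold and z-score binder calling, N-glycan
#' classification and per-class summary — the end-to-end array workflow.
#' Unparseable structure strings are excluded from classification and
#' counted.
#'
#' @param dataset Long array tibble (see [read_array_csv()]) or a CSV path.
#' @param trim Replicates trimmed from each tail.
#' @param rank_threshold Average-rank binder cutoff (strict).
#' @param z_threshold z-score binder cutoff.
#' @param output_dir Optional directory for CSV/JSON artifacts plus a
#'   machine-readable run log.
#' @return List with `rank_table`, `binders_by_rank`, `partition` (per
#'   concentration: binders/non-binders/z), `classes` (tibble from
#'   [classify_report()] or `NULL` if no structures), `motif_summary`,
#'   `n_unparseable`.
#' @export
run_array_pipeline <- function(dataset, trim = 1L, rank_threshold = 10,
                               z_threshold = 1.5, output_dir = NULL) {
  if (is.character(dataset)) dataset <- read_array_csv(dataset)
  tab <- rank_table(dataset, trim = trim)
  binders <- select_binders_by_rank(tab, rank_threshold)

  concs <- attr(tab, "concentrations")
  partition <- lapply(concs, function(cc) {
    means <- setNames(tab[[paste0("mean_", cc)]], tab$glycan_id)
    zscore_binders(means, z_threshold)
  })
  names(partition) <- as.character(concs)

  classes <- NULL; summary <- NULL; n_unparseable <- 0L
  if ("structure" %in% names(tab)) {
    classes <- classify_report(tab$glycan_id, tab$structure)
    n_unparseable <- sum(is.na(classes$class))
    ok <- !is.na(classes$class)
    if (any(ok)) {
      cls <- setNames(classes$class[ok], as.character(classes$glycan_id[ok]))
      summary <- motif_summary(tab[tab$glycan_id %in% classes$glycan_id[ok], ],
                               cls)
    }
  }
  if (!is.null(output_dir)) {
    .write_run_log(output_dir, list(stage = "array", trim = trim,
                                    rank_threshold = rank_threshold,
                                    z_threshold = z_threshold))
    write_rank_csv(tab, file.path(output_dir, "rank_table.csv"))
    write_partition_json(partition, file.path(output_dir, "binders.json"))
    if (!is.null(classes))
      readr::write_csv(classes, file.path(output_dir, "classes.csv"))
  }
  list(rank_table = tab, binders_by_rank = binders, partition = partition,
       classes = classes, motif_summary = summary,
       n_unparseable = n_unparseable)
}

#' Fit an ITC experiment end to end
#'
#' [fit_one_site()] followed by [thermodynamics()] at the scheme's
#' temperature; optionally writes a single JSON artifact.
#'
#' @param isotherm Isotherm tibble, or a CSV path with columns
#'   `injection_volume` and `heat`.
#' @param scheme A [titration_scheme()].
#' @param init Optional starting [one_site_params()].
#' @param output_dir Optional artifact directory.
#' @return List with `fit` (`one_site_fit`) and `thermo` (from
#'   [thermodynamics()]).
#' @export
run_itc <- function(isotherm, scheme, init = NULL, output_dir = NULL) {
  if (is.character(isotherm)) {
    df <- readr::read_csv(isotherm, show_col_types = FALSE)
    if (!all(c("injection_volume", "heat") %in% names(df)))
      stop("ITC CSV needs columns injection_volume, heat", call. = FALSE)
    scheme$injection_volumes <- df$injection_volume
    st <- .itc_state(scheme, cumsum(df$injection_volume))
    isotherm <- tibble::tibble(injection = seq_len(nrow(df)),
                               volume = df$injection_volume,
                               molar_ratio = st$Xt / st$Mt, heat = df$heat)
  }
  fit <- fit_one_site(isotherm, scheme, init = init)
  thermo <- thermodynamics(fit$params, scheme$temperature)
  if (!is.null(output_dir)) {
    .write_run_log(output_dir, list(stage = "itc",
                                    temperature = scheme$temperature))
    out <- c(thermo,
             list(se_n = fit$se[["n"]], se_Ka = fit$se[["Ka"]],
                  se_dH = fit$se[["dH"]], valency = fit$valency,
                  converged = fit$converged))
    jsonlite::write_json(out, file.path(output_dir, "itc_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fit = fit, thermo = thermo)
}

#' Scan sequences for CRS consensus sites
#'
#' Core and extended consensus scans with downstream flagging and, when
#' domain spans are supplied, per-domain counts — the sequence
#' characterization stage of the workflow.
#'
#' @param seqs Named character vector of protein sequences, or a FASTA path.
#' @param domains Optional [domain_spans()] (applied to every sequence).
#' @param hydrophobic Hydrophobic set for [scan_extended()].
#' @param offset Downstream diagnostic offset.
#' @param output_dir Optional artifact directory.
#' @return List with `matches` (tibble over all sequences: `seq_id`,
#'   coordinates, `extended`, `downstream`, `flag`) and `domain_counts`
#'   (named list per sequence, or `NULL`).
#' @export
run_crs <- function(seqs, domains = NULL,
                    hydrophobic = default_hydrophobic(), offset = 1L,
                    output_dir = NULL) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    core <- scan_crs(seqs[[id]])
    ext <- scan_extended(seqs[[id]], hydrophobic)
    m <- dplyr::bind_rows(core, ext[, names(core)])
    if (nrow(m)) m <- downstream_flag(seqs[[id]], m, offset)
    dplyr::bind_cols(tibble::tibble(seq_id = rep(id, nrow(m))), m)
  })
  matches <- dplyr::bind_rows(rows)
  domain_counts <- NULL
  if (!is.null(domains)) {
    domain_counts <- lapply(seqs, function(s) crs_per_domain(s, domains))
    names(domain_counts) <- names(seqs)
  }
  if (!is.null(output_dir)) {
    .write_run_log(output_dir, list(stage = "crs", offset = offset,
                                    hydrophobic = hydrophobic))
    readr::write_tsv(matches, file.path(output_dir, "crs_matches.tsv"))
    if (!is.null(domain_counts))
      jsonlite::write_json(domain_counts,
                           file.path(output_dir, "domain_counts.json"),
                           auto_unbox = FALSE, pretty = TRUE)
  }
  list(matches = matches, domain_counts = domain_counts)
}

#' Build an NJ tree from an aligned FASTA
#'
#' [diff_distance()] (number of differences, complete deletion) followed by
#' [neighbor_joining()]; optionally writes the newick tree and the distance
#' matrix.
#'
#' @param alignment Named character vector of aligned sequences, or a FASTA
#'   path.
#' @param output_dir Optional artifact directory.
#' @return List with `distances` (matrix) and `tree` (`phylo`).
#' @export
run_nj <- function(alignment, output_dir = NULL) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment))
    alignment <- read_fasta(alignment, aligned = TRUE)
  d <- diff_distance(alignment)
  tree <- neighbor_joining(d)
  if (!is.null(output_dir)) {
    .write_run_log(output_dir, list(stage = "nj", n_taxa = nrow(d)))
    utils::write.csv(d, file.path(output_dir, "distances.csv"))
    ape::write.tree(tree, file.path(output_dir, "tree.nwk"))
  }
  list(distances = d, tree = tree)
}
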