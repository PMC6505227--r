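#' Trimmed replicate summary of spot intensities
#'
#' Negative relative-fluorescence values are floored at zero, then the `trim`
#' highest and `trim` lowest replicates are dropped (the usual CFG array
#' convention is 1 of 6) and the mean and sample SD of the remainder are
#' returned.
#'
#' @param rfus Numeric replicate RFUs for one spot.
#' @param trim Number of high and of low replicates to drop.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
summarize_replicates <- function(rfus, trim = 1L) {
  stopifnot(is.numeric(rfus), trim >= 0)
  if (length(rfus) <= 2 * trim)
    stop(sprintf("too few replicates (%d) for trim = %d", length(rfus), trim),
         call. = FALSE)
  x <- sort(pmax(rfus, 0))
  if (trim > 0) x <- x[(trim + 1):(length(x) - trim)]
  c(mean = mean(x), sd = sd(x))
}

#' Percent-of-maximum normalization at one lectin concentration
#'
#' Each glycan's score is 100 times its mean RFU divided by the maximum mean
#' RFU at that concentration, so at least one glycan scores 100 and all
#' scores lie in \[0, 100\]. Scores are invariant under uniform rescaling of
#' the RFUs at a concentration.
#'
#' @param means Named numeric vector of per-glycan mean RFUs.
#' @return Named numeric vector of scores in \[0, 100\].
#' @export
percent_of_max <- function(means) {
  stopifnot(is.numeric(means))
  m <- pmax(means, 0)
  top <- max(m)
  if (!is.finite(top) || top <= 0)
    stop("all mean RFUs are zero at this concentration: uninformative experiment",
         call. = FALSE)
  100 * m / top
}

.check_dataset <- function(dataset) {
  need <- c("glycan_id", "concentration", "rfu")
  if (!all(need %in% names(dataset)))
    stop("array dataset needs columns glycan_id, concentration, rfu (long form)",
         call. = FALSE)
  chk <- dataset |>
    dplyr::count(.data$glycan_id, .data$concentration)
  if (dplyr::n_distinct(chk$n) != 1L)
    stop("unequal replicate counts across glycans/concentrations", call. = FALSE)
  wide <- table(dataset$glycan_id, dataset$concentration) > 0
  if (!all(wide))
    stop("every glycan must be measured at every concentration", call. = FALSE)
  invisible(dataset)
}

#' Rank table: per-concentration scores and average rank
#'
#' For each lectin concentration, replicate RFUs are summarized with
#' [summarize_replicates()] and normalized with [percent_of_max()]; the
#' average rank of a glycan is the arithmetic mean of its per-concentration
#' scores. A glycan that tops every concentration has average rank 100; one
#' that is top at only some concentrations stays below 100.
#'
#' @param dataset Long-form tibble with columns `glycan_id`, `concentration`,
#'   `rfu` and optionally `structure` (see [read_array_csv()]).
#' @param trim Replicates trimmed from each tail (see
#'   [summarize_replicates()]).
#' @return Tibble, one row per glycan sorted by decreasing `average_rank`,
#'   with nested per-concentration columns `mean_<c>`, `sd_<c>`, `score_<c>`.
#' @export
rank_table <- function(dataset, trim = 1L) {
  .check_dataset(dataset)
  per <- dataset |>
    dplyr::group_by(.data$glycan_id, .data$concentration) |>
    dplyr::summarise(mean = summarize_replicates(.data$rfu, trim)[["mean"]],
                     sd = summarize_replicates(.data$rfu, trim)[["sd"]],
                     .groups = "drop") |>
    dplyr::group_by(.data$concentration) |>
    dplyr::mutate(score = percent_of_max(setNames(.data$mean,
                                                  .data$glycan_id))) |>
    dplyr::ungroup()
  wide <- per |>
    tidyr::pivot_wider(id_cols = "glycan_id",
                       names_from = "concentration",
                       values_from = c("mean", "sd", "score"))
  avg <- per |>
    dplyr::group_by(.data$glycan_id) |>
    dplyr::summarise(average_rank = mean(.data$score), .groups = "drop")
  out <- dplyr::left_join(wide, avg, by = "glycan_id") |>
    dplyr::arrange(dplyr::desc(.data$average_rank))
  if ("structure" %in% names(dataset)) {
    st <- dplyr::distinct(dataset, .data$glycan_id, .data$structure)
    out <- dplyr::left_join(out, st, by = "glycan_id") |>
      dplyr::relocate("structure", .after = "glycan_id")
  }
  attr(out, "concentrations") <- sort(unique(dataset$concentration),
                                      decreasing = TRUE)
  out
}

#' Average of per-concentration scores
#'
#' @param scores Numeric matrix or data frame, glycans in rows and one column
#'   per concentration, or a list of equally-named score vectors.
#' @return Named numeric vector of average ranks, sorted decreasing.
#' @export
average_rank <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    nm <- lapply(scores, names)
    if (length(unique(lapply(nm, sort))) != 1L)
      stop("mismatched glycan sets across concentrations", call. = FALSE)
    scores <- do.call(cbind, lapply(scores, function(s) s[names(scores[[1]])]))
  }
  scores <- as.matrix(scores)
  sort(rowMeans(scores), decreasing = TRUE)
}

#' Select binders by average-rank threshold
#'
#' @param table A [rank_table()] result.
#' @param threshold Rank-unit cutoff; glycans strictly above it are returned.
#' @return Vector of glycan ids in decreasing average-rank order.
#' @export
select_binders_by_rank <- function(table, threshold = 10) {
  stopifnot(is.data.frame(table), "average_rank" %in% names(table))
  tab <- dplyr::arrange(table, dplyr::desc(.data$average_rank))
  tab$glycan_id[tab$average_rank > threshold]
}

#' z-score binder/non-binder partition at one concentration
#'
#' Mean RFUs are log-transformed (`log(mean + 1)`), standardized over all
#' glycans, and glycans at or above `z_threshold` are called binders, in the
#' spirit of the GlycoPattern z-score partition. The partition is exhaustive
#' and disjoint. With zero spread all glycans are non-binders and a warning
#' is emitted.
#'
#' @param means Named numeric vector of per-glycan mean RFUs.
#' @param z_threshold Standardized-score cutoff (default 1.5).
#' @return List with `binders`, `non_binders` (glycan names) and `z` (named
#'   scores).
#' @export
zscore_binders <- function(means, z_threshold = 1.5) {
  stopifnot(is.numeric(means), length(means) >= 3, !is.null(names(means)))
  t <- log(pmax(means, 0) + 1)
  s <- sd(t)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in log RFUs: no binders called")
    z <- setNames(rep(0, length(t)), names(means))
    return(list(binders = character(0), non_binders = names(means), z = z))
  }
  z <- (t - mean(t)) / s
  names(z) <- names(means)
  list(binders = names(means)[z >= z_threshold],
       non_binders = names(means)[z < z_threshold],
       z = z)
}

#' Per-class summary of average ranks
#'
#' @param table A [rank_table()] result.
#' @param classes Named character vector mapping glycan id to N-glycan class
#'   (e.g. from [classify_report()]).
#' @return Tibble with `class`, `n`, `mean_rank`, `median_rank`, ordered by
#'   decreasing mean rank.
#' @export
motif_summary <- function(table, classes) {
  stopifnot(all(as.character(table$glycan_id) %in% names(classes)))
  tibble::tibble(glycan_id = table$glycan_id,
                 average_rank = table$average_rank,
                 class = unname(classes[as.character(table$glycan_id)])) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_rank = mean(.data$average_rank),
                     median_rank = median(.data$average_rank),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_rank))
}
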