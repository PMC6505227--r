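test_that("replicate summaries trim extremes and floor negatives", {
  s <- summarize_replicates(c(100, 110, 90, 5000, 105, 95), trim = 1)
  expect_equal(s[["mean"]], 102.5)
  expect_equal(summarize_replicates(c(50, 50, 50), trim = 0),
               c(mean = 50, sd = 0))
  s2 <- summarize_replicates(c(-20, 10, 10, 10), trim = 0)
  expect_equal(s2[["mean"]], 7.5)
  expect_error(summarize_replicates(c(1, 2), trim = 1), "too few")
})

test_that("percent-of-max normalization scores 0-100 with one at 100", {
  sc <- percent_of_max(c(A = 2000, B = 1000, C = 0))
  expect_equal(sc, c(A = 100, B = 50, C = 0))
  expect_equal(unname(percent_of_max(c(x = 7, y = 7))), c(100, 100))
  expect_error(percent_of_max(c(a = 0, b = 0)), "uninformative")
})

test_that("average rank is the mean of per-concentration scores", {
  sc <- list(c(g1 = 100, g2 = 50), c(g1 = 80, g2 = 50), c(g1 = 60, g2 = 50))
  avg <- average_rank(sc)
  expect_equal(avg[["g1"]], 80)
  expect_equal(avg[["g2"]], 50)
  expect_equal(names(avg), c("g1", "g2"))  # sorted descending
  bad <- list(c(g1 = 1, g2 = 2), c(g1 = 1, g3 = 2))
  expect_error(average_rank(bad), "mismatched")
})

test_that("rank-threshold selection is strict and ordered", {
  tab <- tibble::tibble(glycan_id = c("a", "b", "c"),
                        average_rank = c(12, 10, 3))
  expect_equal(select_binders_by_rank(tab, 10), "a")
  expect_equal(select_binders_by_rank(tab, 0), c("a", "b", "c"))
  expect_equal(select_binders_by_rank(tab, 100), character(0))
})

test_that("z-score partition is exhaustive, disjoint, and flags outliers", {
  means <- c(setNames(rlnorm(99, log(100), 0.2), paste0("g", 1:99)),
             big = 1e6)
  part <- zscore_binders(means, z_threshold = 1.5)
  expect_true("big" %in% part$binders)
  expect_length(intersect(part$binders, part$non_binders), 0)
  expect_setequal(c(part$binders, part$non_binders), names(means))
  expect_warning(p0 <- zscore_binders(c(a = 5, b = 5, c = 5)), "zero spread")
  expect_length(p0$binders, 0)
})

test_that("scores are invariant to uniform rescaling at a concentration", {
  lib <- gen_glycan_library(30, seed = 21)
  arr <- gen_array_rfus(lib$glycans, binder_ids = 1:5, seed = 22)
  tab1 <- rank_table(arr$dataset)
  scaled <- arr$dataset
  scaled$rfu <- scaled$rfu * ifelse(scaled$concentration == 1, 37.5, 1)
  tab2 <- rank_table(scaled)
  expect_equal(tab2$average_rank, tab1$average_rank)
  expect_equal(tab2$score_1, tab1$score_1)
})

test_that("permuting glycan order permutes outputs identically", {
  lib <- gen_glycan_library(20, seed = 23)
  arr <- gen_array_rfus(lib$glycans, binder_ids = 1:3, seed = 24)
  tab1 <- rank_table(arr$dataset)
  perm <- arr$dataset[sample(nrow(arr$dataset)), ]
  tab2 <- rank_table(perm)
  expect_equal(tab2[order(tab2$glycan_id), ], tab1[order(tab1$glycan_id), ])
})

test_that("dataset validation catches missing cells and ragged replicates", {
  lib <- gen_glycan_library(5, seed = 25)
  arr <- gen_array_rfus(lib$glycans, binder_ids = integer(0), seed = 26)
  expect_error(rank_table(arr$dataset[-1, ]), "replicate|concentration")
  drop_conc <- dplyr::filter(arr$dataset,
                             !(glycan_id == 1 & concentration == 10))
  expect_error(rank_table(drop_conc), "every (glycan|concentration)")
})

test_that("per-class summary ranks planted high-mannose binders on top", {
  lib <- gen_glycan_library(40, planted = rep(CORE_STRING, 8),
                            decorate = 0, seed = 27)
  arr <- gen_array_rfus(lib$glycans, binder_ids = 1:8, seed = 28)
  res <- run_array_pipeline(arr$dataset)
  expect_equal(res$motif_summary$class[1], "high_mannose")
  one <- motif_summary(res$rank_table,
                       setNames(rep("x", nrow(res$rank_table)),
                                res$rank_table$glycan_id))
  expect_equal(nrow(one), 1)
})
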