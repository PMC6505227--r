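test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_glycan_library(25, planted = rep(CORE_STRING, 5), seed = 7)
  b <- gen_glycan_library(25, planted = rep(CORE_STRING, 5), seed = 7)
  expect_identical(a, b)
  c <- gen_glycan_library(25, planted = rep(CORE_STRING, 5), seed = 8)
  expect_false(identical(a$glycans$structure, c$glycans$structure))

  x <- gen_array_rfus(a$glycans, binder_ids = 1:5, seed = 9)
  y <- gen_array_rfus(a$glycans, binder_ids = 1:5, seed = 9)
  expect_identical(x, y)

  s1 <- gen_lectin_seq(seed = 10)
  s2 <- gen_lectin_seq(seed = 10)
  expect_identical(s1, s2)

  i1 <- gen_isotherm(params = one_site_params(0.32, 1e6, -1e4), seed = 11)
  i2 <- gen_isotherm(params = one_site_params(0.32, 1e6, -1e4), seed = 11)
  expect_identical(i1, i2)
})

test_that("generated glycan strings always reparse (grammar closure)", {
  lib <- gen_glycan_library(100, planted = rep(CORE_STRING, 10), seed = 13)
  parsed <- parse_glycans(lib$glycans$structure)
  expect_equal(nrow(parsed$errors), 0)
  expect_false(any(vapply(parsed$trees, is.null, logical(1))))
})

test_that("planted motifs survive decoration and classify as core glycans", {
  lib <- gen_glycan_library(100, planted = rep(CORE_STRING, 10), seed = 14)
  rep <- classify_report(lib$glycans$glycan_id, lib$glycans$structure)
  expect_gte(sum(rep$class != "non_core"), 10)
  expect_true(all(rep$core[lib$truth$planted]))
  one <- gen_glycan_library(1, seed = 15)
  expect_s3_class(parse_glycan(one$glycans$structure), "glycan_tree")
})

test_that("array generator controls noise and binder contrast", {
  lib <- gen_glycan_library(12, seed = 16)
  silent <- gen_array_rfus(lib$glycans, binder_ids = 1:2, noise_sigma = 0,
                           seed = 17)
  spread <- silent$dataset |>
    dplyr::group_by(glycan_id, concentration) |>
    dplyr::summarise(v = stats::var(rfu), .groups = "drop")
  expect_true(all(spread$v < 1e-18))
  # fold = 1 leaves binders indistinguishable in expectation
  flat <- gen_array_rfus(lib$glycans, binder_ids = integer(0), fold = 1,
                         seed = 18)
  expect_equal(sort(unique(flat$dataset$concentration)), c(0.1, 1, 10))
  expect_equal(nrow(flat$dataset), 12 * 3 * 6)
})

test_that("noise-free isotherms equal the forward model", {
  p <- one_site_params(0.32, 1e6, -1e4)
  g <- gen_isotherm(params = p, noise_frac = 0, seed = 19)
  expect_equal(g$isotherm$heat, simulate_isotherm(titration_scheme(), p)$heat)
  expect_equal(nrow(g$isotherm), 18)  # default injection schedule
})

test_that("lectin generator plants exactly the requested CRS profile", {
  atl_like <- gen_lectin_seq(crs_counts = c(1L, 1L), downstream = "Q",
                             seed = 20)
  expect_equal(unname(crs_per_domain(atl_like$record$sequence,
                                     atl_like$domains)), c(1L, 1L))
  fl <- downstream_flag(atl_like$record$sequence,
                        scan_crs(atl_like$record$sequence))
  expect_true(all(fl$flag == "substituted"))

  gna_like <- gen_lectin_seq(crs_counts = c(3L, 3L), downstream = "A",
                             seed = 21)
  expect_equal(unname(crs_per_domain(gna_like$record$sequence,
                                     gna_like$domains)), c(3L, 3L))
  fl2 <- downstream_flag(gna_like$record$sequence,
                         scan_crs(gna_like$record$sequence))
  expect_true(all(fl2$flag == "mannose-type"))

  none <- gen_lectin_seq(crs_counts = c(0L, 0L), seed = 22)
  expect_equal(nrow(scan_crs(none$record$sequence)), 0)
  # planted sites also satisfy the extended consensus
  expect_equal(nrow(scan_extended(atl_like$record$sequence)), 2)
})

test_that("alignment generator yields testable alignments with gaps", {
  g <- gen_alignment(n_taxa = 5, n_sites = 80, gap_frac = 0.1, seed = 23)
  expect_length(g$alignment, 5)
  expect_equal(unique(nchar(g$alignment)), 80)
  expect_gt(sum(vapply(strsplit(g$alignment, ""),
                       function(x) sum(x == "-"), numeric(1))), 0)
  d <- diff_distance(g$alignment)
  expect_true(isSymmetric(d))
})
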