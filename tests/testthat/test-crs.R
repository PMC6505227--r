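test_that("core consensus scan finds planted and overlapping 9-mers", {
  s <- paste0("MSTKLL", "QGDCNLVLY", "GARST")
  m <- scan_crs(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 7L)
  expect_equal(m$match, "QGDCNLVLY")
  expect_equal(nrow(scan_crs(strrep("A", 30))), 0)
  # overlapping sites are all reported
  s2 <- "QQDDNNVVYY"  # QXDXNXVXY at both 1 and 2
  expect_equal(scan_crs(s2)$start, c(1L, 2L))
  expect_error(scan_crs("QADAN"), "shorter")
})

test_that("extended consensus restricts the lead and hydrophobic positions", {
  expect_equal(nrow(scan_extended("LQGDCNLVIY")), 1)
  ge <- scan_extended("GQGDCNLVIY")
  expect_equal(nrow(ge), 0)
  # the core 9-mer at offset 2 is still found
  expect_equal(scan_crs("GQGDCNLVIY")$start, 2L)
  # hydrophobic set is configurable
  expect_equal(nrow(scan_extended("LQGDCNSVIY")), 0)
  expect_equal(nrow(scan_extended("LQGDCNSVIY", hydrophobic = c("S", "I"))), 1)
  m <- scan_extended("KLQGDCNLVIYR")
  expect_equal(m$core_start, m$start + 1L)
  expect_equal(m$triplet, "LVI")
})

test_that("every extended match implies a core match at offset +1", {
  set.seed(61)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  hyd <- default_hydrophobic()
  n_ext <- 0L
  for (k in 1:200) {
    s <- sample(aa, 60, replace = TRUE)
    if (k %% 2 == 0) {
      # plant one extended site so the implication is exercised, not vacuous
      p <- sample(1:50, 1)
      s[p:(p + 9)] <- c(sample(c("M", "I", "L", "V"), 1), "Q", sample(aa, 1),
                        "D", sample(aa, 1), "N", sample(hyd, 1), "V",
                        sample(hyd, 1), "Y")
    }
    str <- paste(s, collapse = "")
    ext <- scan_extended(str)
    core <- scan_crs(str)
    n_ext <- n_ext + nrow(ext)
    expect_true(all((ext$start + 1L) %in% core$start), info = str)
  }
  expect_gte(n_ext, 100)
})

test_that("matches count for a domain only when fully contained", {
  g <- gen_lectin_seq(crs_counts = c(1L, 1L), downstream = "Q", seed = 101)
  expect_equal(unname(crs_per_domain(g$record$sequence, g$domains)),
               c(1L, 1L))
  expect_length(crs_per_domain(g$record$sequence,
                               domain_spans(character(0), integer(0),
                                            integer(0))), 0)
  # a motif straddling a boundary counts in neither domain
  s <- paste0(strrep("G", 10), "QGDCNLVLY", strrep("G", 10))
  halves <- domain_spans(c("L", "R"), c(1, 15), c(14, 29))
  expect_equal(unname(crs_per_domain(s, halves)), c(0L, 0L))
  expect_error(crs_per_domain(s, domain_spans("X", 1, 99)), "beyond")
})

test_that("downstream residue flags the mannose-binding diagnostic", {
  for (case in list(c("A", "mannose-type"), c("Q", "substituted"),
                    c("G", "other"))) {
    s <- paste0("MM", "QGDCNLVLY", case[1], "RR")
    fl <- downstream_flag(s, scan_crs(s), offset = 1)
    expect_equal(fl$downstream, case[1])
    expect_equal(fl$flag, case[2])
  }
  s <- paste0("MM", "QGDCNLVLY")
  expect_error(downstream_flag(s, scan_crs(s), offset = 1), "beyond")
})

test_that("reversed sequences lose non-palindromic motifs", {
  g <- gen_lectin_seq(crs_counts = c(2L, 2L), seed = 103)
  s <- g$record$sequence
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_gt(nrow(scan_crs(s)), 0)
  expect_equal(nrow(scan_crs(rev_s)), 0)
})

test_that("domain counts are invariant to flanking sequence", {
  g <- gen_lectin_seq(crs_counts = c(1L, 2L), seed = 104)
  s <- g$record$sequence
  counts <- crs_per_domain(s, g$domains)
  flank <- strrep("G", 17)
  shifted <- g$domains
  shifted$start <- shifted$start + nchar(flank)
  shifted$end <- shifted$end + nchar(flank)
  expect_equal(crs_per_domain(paste0(flank, s, flank), shifted), counts)
})

test_that("sequence properties compute protein mass and GC percent", {
  p <- seq_properties("G", type = "protein")
  expect_equal(p$mass_da, 75.07, tolerance = 1e-4)
  expect_equal(seq_properties("GGCC")$gc_percent, 100.0)
  expect_equal(seq_properties("ATGC")$gc_percent, 50.0)
  expect_equal(seq_properties("ATGCATGCAT")$gc_percent, 40.0)
  expect_error(seq_properties("MANB1J", type = "protein"), "alphabet")
  expect_error(seq_properties("ACGTX", type = "nucleotide"), "alphabet")
  # 257-residue synthetic lectin precursor is in the tens of kDa
  g <- gen_lectin_seq(seed = 105)
  pr <- seq_properties(g$record$sequence, type = "protein")
  expect_equal(pr$length, 257)
  expect_gt(pr$mass_da, 2e4)
  expect_lt(pr$mass_da, 3.5e4)
})
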