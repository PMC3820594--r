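test_that("minimal motif matches and non-matches behave", {
  expect_equal(scan_motif("YAGQ")$start, 0L)
  expect_equal(nrow(scan_motif(strrep("KKKK", 25))), 0L)
  five <- strrep("LQTLYAGQLLLLL", 5)
  hits <- scan_motif(five)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$start, oracle_scan_motif(five))
})

test_that("scanner agrees with the all-position oracle and hits never overlap", {
  withr::with_seed(23, {
    for (rep in 1:50) {
      seq <- random_aa_seq(400)
      got <- scan_motif(seq)$start
      expect_equal(got, oracle_scan_motif(seq))
      if (length(got) >= 2L) expect_true(all(diff(got) >= 4L))
    }
  })
})

test_that("density follows the printed definition and is filler-invariant", {
  hits <- data.frame(protein_id = "p", start = c(0, 20, 40, 60, 80),
                     matched_text = "YAGQ")
  expect_identical(motif_density(hits, 100L), 0.05)
  expect_identical(motif_density(hits[0, ], 57L), 0)
  expect_error(motif_density(hits, 0L), "positive")

  p <- make_zf_protein("p", n_repeats = 50L, seed = 3)
  hits <- scan_motif(p)
  expect_equal(motif_density(hits, nchar(p$sequence)), 50 / nchar(p$sequence))
})

test_that("segment extension emits 14-residue windows and drops truncated hits", {
  # one interior hit
  p <- paste0(strrep("L", 5), "YAGQ", strrep("L", 5))
  segs <- extend_segments(scan_motif(p), p)
  expect_equal(segs, p)
  expect_equal(nchar(segs), 14L)
  # hit at position 0 is dropped
  expect_length(extend_segments(scan_motif("YAGQLLLLLLLL"), "YAGQLLLLLLLL"), 0L)
  # k interior + m boundary hits -> exactly k segments
  q <- paste0("YAGQ", strrep("L", 10), "YAGQ", strrep("L", 10), "YAGQ")
  hits <- scan_motif(q)
  expect_equal(nrow(hits), 3L)
  expect_length(extend_segments(hits, q), 1L)
})

test_that("the position-frequency matrix conserves counts and information", {
  seg <- "LQTLQYAGQLLKPS"
  pfm1 <- build_pfm(seg)
  expect_true(all(rowSums(pfm1$counts) == 1L))
  expect_equal(unname(pfm1$info), rep(log2(20), 14), tolerance = 1e-12)
  pfm2 <- build_pfm(c(seg, seg))
  expect_true(all(rowSums(pfm2$counts) == 2L))
  expect_equal(unname(pfm2$info), rep(log2(20), 14), tolerance = 1e-12)
  expect_equal(sum(pfm2$counts), 14L * 2L)
  expect_error(build_pfm(c(seg, "SHORT")), "mixed")
})

test_that("position-1 Y frequency of generated segments sits in binomial bounds", {
  # 100 segments from the generator at Y:C odds 9:1; exact binomial 99% band
  p <- make_zf_protein("yfrac", n_repeats = 100L, seed = 91, y_prob = 0.9)
  prof <- repeat_profile(p)
  expect_equal(prof$n_hits, 100L)
  band <- qbinom(c(0.005, 0.995), 100, 0.9) / 100
  expect_gte(prof$y_fraction, band[1])
  expect_lte(prof$y_fraction, band[2])
  # the motif column of the pfm: position 6 of the 14-mer is the [YC] slot
  yc_counts <- prof$pfm$counts[6, c("Y", "C")]
  expect_equal(sum(yc_counts), prof$pfm$n_segments)
})

test_that("tandem runs match the maximal-chain oracle", {
  mk <- function(starts) data.frame(protein_id = "p", start = starts,
                                    matched_text = "YAGQ")
  runs <- find_tandem_runs(mk(seq(0, by = 14, length.out = 5)))
  expect_length(runs, 1L)
  expect_equal(runs[[1]]$indices, 1:5)
  expect_length(find_tandem_runs(mk(seq(0, by = 50, length.out = 4))), 0L)

  withr::with_seed(7, {
    for (rep in 1:20) {
      gaps <- sample(c(10:18, 30, 50), 15, replace = TRUE)
      starts <- cumsum(c(0, gaps))
      got <- lapply(find_tandem_runs(mk(starts)), `[[`, "indices")
      expect_equal(got, oracle_tandem_runs(starts))
    }
  })
})

test_that("proteome ranking orders by density and separates Y-start from C-start families", {
  rich <- make_zf_protein("rich", n_repeats = 30L, seed = 12)
  keratin <- make_zf_protein("keratin_like", n_repeats = 20L, seed = 13, y_prob = 0)
  bare <- protein_record("bare", strrep("LAKE", 100))
  tab <- rank_proteome(list(rich, keratin, bare))
  expect_equal(tab$id[1], "rich")
  expect_equal(tab$id[3], "bare")
  expect_equal(tab$y_fraction[tab$id == "keratin_like"], 0)
  expect_gt(tab$y_fraction[tab$id == "rich"], 0.5)

  # ranking equals an independent recompute-and-sort
  withr::with_seed(31, {
    prots <- lapply(1:40, function(i) {
      make_zf_protein(sprintf("p%02d", i), n_repeats = sample(0:20, 1),
                      seed = 5000 + i)
    })
    tab <- rank_proteome(prots)
    dens <- vapply(prots, function(p) {
      length(oracle_scan_motif(p$sequence)) / nchar(p$sequence)
    }, numeric(1))
    ids <- vapply(prots, `[[`, character(1), "id")
    want <- ids[order(-dens, ids)]
    expect_equal(tab$id, want)
  })
})
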