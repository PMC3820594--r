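make_test_locus <- function(seed, intron = "GT_AG_between_f1_f2", ...) {
  prot <- make_zf_protein(paste0("L", seed), n_repeats = 5L,
                          seed = seed * 31L + 7L)
  make_locus(prot, intron_plan = intron, seed = seed, ...)
}

test_that("frame hits round-trip through translation on both strands", {
  loc <- make_test_locus(101)
  for (dna in list(loc$dna,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(loc$dna))))) {
    hits <- six_frame_scan(dna)
    expect_gt(length(hits), 0L)
    for (h in hits) {
      expect_equal((h$g_end - h$g_start) %% 3, 0)
      expect_equal(h$peptide, oracle_hit_peptide(h, dna))
    }
  }
})

test_that("reverse-complement scanning mirrors hit coordinates exactly", {
  loc <- make_test_locus(102, intron = "none")
  hits_f <- six_frame_scan(loc$dna)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(loc$dna)))
  hits_r <- six_frame_scan(rc)
  L <- nchar(loc$dna)
  key <- function(hs) {
    m <- t(vapply(hs, function(h) c(h$g_start, h$g_end), numeric(2)))
    m[order(m[, 1]), , drop = FALSE]
  }
  mirrored <- t(vapply(hits_r, function(h) c(L - h$g_end, L - h$g_start), numeric(2)))
  mirrored <- mirrored[order(mirrored[, 1]), , drop = FALSE]
  expect_equal(key(hits_f), mirrored)
  expect_setequal(vapply(hits_f, `[[`, character(1), "peptide"),
                  vapply(hits_r, `[[`, character(1), "peptide"))
})

test_that("scan results agree with a per-frame brute-force oracle on random DNA", {
  withr::with_seed(55, {
    dna <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  })
  hits <- six_frame_scan(dna)
  n_oracle <- 0L
  for (tr in translate_six_frames(dna)) {
    n_oracle <- n_oracle + nrow(oracle_find_fingers(tr$peptide, allow_stop = TRUE))
  }
  expect_equal(sum(vapply(hits, `[[`, integer(1), "n_fingers")), n_oracle)
})

test_that("intron structure classification distinguishes canonical splices", {
  m_int <- with(make_test_locus(103), assemble_gene_model(six_frame_scan(dna), dna))
  expect_equal(m_int$intron_structure, "intron_containing")
  expect_equal(length(m_int$segments), 2L)

  m_none <- with(make_test_locus(104, intron = "none"),
                 assemble_gene_model(six_frame_scan(dna), dna))
  expect_equal(m_none$intron_structure, "intronless")
  expect_equal(length(m_none$segments), 1L)
  expect_equal(m_none$segments[[1]]$n_fingers, 3L)

  m_bad <- with(make_test_locus(105, intron = "CT_AC_between_f1_f2"),
                assemble_gene_model(six_frame_scan(dna), dna))
  expect_equal(m_bad$intron_structure, "unknown")
})

test_that("status calls recover planted truth: stops, deteriorated anchors, clean loci", {
  loc_stop <- make_test_locus(106, pseudogenize = 2L)
  m <- assemble_gene_model(six_frame_scan(loc_stop$dna), loc_stop$dna)
  expect_equal(call_status(m), "pseudogene")
  expect_true(loc_stop$truth$stop_genomic %in% m$premature_stops)

  loc_anchor <- make_test_locus(107, intron = "none", pseudogenize = "anchor")
  m2 <- assemble_gene_model(six_frame_scan(loc_anchor$dna), loc_anchor$dna)
  expect_equal(call_status(m2), "pseudogene")
  expect_lt(m2$total_fingers, 3L)

  loc_clean <- make_test_locus(108, intron = "none")
  m3 <- assemble_gene_model(six_frame_scan(loc_clean$dna), loc_clean$dna)
  expect_equal(call_status(m3), "coding")
  expect_length(m3$premature_stops, 0L)
})

test_that("repeat-region similarity is detected in masked loci but not in random DNA", {
  loc <- make_test_locus(109, mask_fingers = TRUE)
  expect_true(detect_repeat_region(loc$dna))
  m <- assemble_gene_model(six_frame_scan(loc$dna), loc$dna)
  expect_equal(call_status(m), "absent")
  withr::with_seed(99, {
    rand <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = "")
  })
  expect_false(detect_repeat_region(rand))
})

test_that("rising mutation load never increases strict coding calls (in the mean)", {
  rates <- c(0, 0.1, 0.3)
  n_rep <- 20L
  strict_coding <- matrix(0, n_rep, length(rates))
  base <- make_test_locus(110, intron = "none")
  for (i in seq_len(n_rep)) {
    for (j in seq_along(rates)) {
      dna <- mutate_residues(base$dna, rates[j], seed = 7000L + 37L * i + j,
                             alphabet = c("A", "C", "G", "T"))
      model <- assemble_gene_model(six_frame_scan(dna), dna)
      ok <- FALSE
      if (call_status(model) == "coding") {
        pep <- gsub("\\*", "X", paste(vapply(model$segments, `[[`, character(1),
                                             "peptide"), collapse = ""))
        ok <- classify_protein(pep)$label == "SPKLF_STRICT"
      }
      strict_coding[i, j] <- ok
    }
  }
  means <- colMeans(strict_coding)
  expect_equal(means[1], 1)
  expect_true(all(diff(means) <= 0))
})
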