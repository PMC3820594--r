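test_that("the canonical spacing pattern is parsed with its printed gaps", {
  p <- paste0(strrep("A", 10), "C", "AAAA", "C", strrep("A", 12), "H", "AAA", "H")
  f <- find_c2h2_domains(p)
  expect_equal(nrow(f), 1L)
  expect_equal(f$c1, 10L)
  expect_equal(f$cys_gap, 4L)
  expect_equal(f$c2 - f$c1 - 1L, 4L)
  expect_equal(f$h1 - f$c2 - 1L, 12L)
  expect_equal(f$h2 - f$h1 - 1L, 3L)

  expect_equal(nrow(find_c2h2_domains(strrep("A", 60))), 0L)
})

test_that("greedy parse agrees with the all-position enumeration oracle", {
  withr::with_seed(11, {
    for (rep in 1:30) {
      seq <- random_aa_seq(500)
      got <- find_c2h2_domains(seq)
      want <- oracle_find_fingers(seq)
      expect_equal(got[, c("c1", "c2", "h1", "h2", "cys_gap")], want,
                   ignore_attr = TRUE)
    }
    # planted consensus finger in an otherwise finger-free background
    bg <- gsub("[CH]", "A", random_aa_seq(500))
    planted <- paste0(substr(bg, 1, 200),
                      "C", "GGGG", "C", strrep("G", 12), "H", "GGG", "H",
                      substr(bg, 201, 500))
    f <- find_c2h2_domains(planted)
    expect_equal(nrow(f), 1L)
    expect_equal(f$c1, 200L)
    expect_equal(f, oracle_find_fingers(planted)[, names(f)[1:5]] |>
                   cbind(inner_gap = 12L, his_gap = 3L), ignore_attr = TRUE)
  })
})

test_that("signatures separate family spacing patterns", {
  sig <- function(p) classify_protein(p)
  expect_equal(sig(spaced_finger_protein(c(4, 4, 2)))$label, "SPKLF_STRICT")
  expect_equal(sig(spaced_finger_protein(c(4, 4, 2)))$cys_gaps, c(4L, 4L, 2L))
  expect_equal(sig(spaced_finger_protein(c(4, 2, 2)))$label, "EGR_LIKE")
  expect_equal(sig(spaced_finger_protein(c(2, 2, 2)))$label, "SPKLF_RELAXED")
  expect_equal(sig(spaced_finger_protein(c(4, 4, 2, 4)))$label, "WT1_LIKE")
  expect_equal(sig(strrep("A", 50))$label, "NO_C2H2")
  # non-canonical linkers demote a consensus spacing to OTHER
  expect_equal(sig(spaced_finger_protein(c(4, 4, 2), linker = 10))$label,
               "OTHER_C2H2")
  expect_error(signature_of(data.frame(c1 = c(0, 5), c2 = c(5, 10),
                                       h1 = c(18, 23), h2 = c(22, 27),
                                       cys_gap = 4, inner_gap = 12, his_gap = 3)),
               "overlap")
})

test_that("labels are recovered on a generated decoy panel", {
  specs <- list(SPKLF_STRICT = c(4, 4, 2), EGR_LIKE = c(4, 2, 2),
                WT1_LIKE = c(4, 4, 2, 4))
  n_each <- 100L
  for (lab in names(specs)) {
    for (i in seq_len(n_each)) {
      p <- make_zf_protein(paste0(lab, i), cys_gaps = specs[[lab]],
                           n_repeats = 0L, seed = 1000L * match(lab, names(specs)) + i)
      expect_equal(classify_protein(p)$label, lab)
    }
  }
})

test_that("a terminal cysteine is accepted in place of the last histidine only when allowed", {
  p <- spaced_finger_protein(c(4, 4, 2), last = "C")
  expect_equal(classify_protein(p)$label, "SPKLF_STRICT")
  relaxed_off <- grammar_params(allow_terminal_cys_for_his = FALSE)
  f <- find_c2h2_domains(p, relaxed_off)
  expect_equal(nrow(f), 2L)   # third finger dropped
})

test_that("contact-residue conservation is scored at the specified offsets", {
  p <- make_zf_protein("klf", seed = 5, n_repeats = 0L)
  f <- find_c2h2_domains(p)
  rep6 <- contact_report(p, f)
  expect_equal(rep6$n_pass, 6L)
  expect_equal(rep6$n_checked, 6L)

  # mutate one planted arginine to lysine: 5/6, and the failure is localized
  spec <- contact_spec()
  arg_row <- which(spec$class == "R")[1]
  pos <- f$c2[spec$finger[arg_row]] + 1L + spec$offset[arg_row]
  chars <- strsplit(p$sequence, "")[[1]]
  expect_equal(chars[pos + 1L], "R")
  chars[pos + 1L] <- "K"
  mutated <- protein_record("mut", paste(chars, collapse = ""))
  rep5 <- contact_report(mutated, f)
  expect_equal(rep5$n_pass, 5L)
  fail <- rep5$checks[!rep5$checks$pass, ]
  expect_equal(fail$finger, spec$finger[arg_row])
  expect_equal(fail$offset, spec$offset[arg_row])
  expect_equal(fail$observed, "K")

  expect_error(contact_report(p, f[1:2, ]), "not applicable")
})

test_that("zinc-finger region extraction matches the coordinate identity", {
  p <- spaced_finger_protein(c(4, 4, 2))
  f <- find_c2h2_domains(p)
  region <- extract_zf_region(p, f)
  expect_equal(nchar(region), f$h2[3] - f$c1[1] + 1L)
  # per-finger spans (cys_gap + 19) plus two 7-residue linkers
  expect_equal(nchar(region), (4L + 19L) + (4L + 19L) + (2L + 19L) + 2L * 7L)
  # reconstruction: region starts and ends on anchors
  expect_equal(substring(region, 1, 1), "C")
  expect_match(substring(region, nchar(region), nchar(region)), "[HC]")
  none <- find_c2h2_domains(strrep("A", 30))
  expect_error(extract_zf_region(p, none), "not applicable")
})
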