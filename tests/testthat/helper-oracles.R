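# Independent brute-force oracles. These deliberately re-derive results by
# enumeration rather than reusing the package's scanning logic.

# Enumerate every grammar match at every start position, then select a
# non-overlapping set left to right (smallest cysteine separation first at
# equal starts). Returns the same columns as find_c2h2_domains.
oracle_find_fingers <- function(seq, cys_gap_range = c(2L, 4L), inner_gap = 12L,
                                his_gap = 3L, allow_terminal_cys = TRUE,
                                allow_stop = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  all_matches <- list()
  for (i in seq_len(n)) {
    if (chars[i] != "C") next
    for (g in cys_gap_range[1]:cys_gap_range[2]) {
      c2 <- i + g + 1L; h1 <- c2 + inner_gap + 1L; h2 <- h1 + his_gap + 1L
      if (h2 > n) next
      if (chars[c2] != "C" || chars[h1] != "H") next
      if (!(chars[h2] == "H" || (allow_terminal_cys && chars[h2] == "C"))) next
      between <- chars[setdiff(i:h2, c(i, c2, h1, h2))]
      if (!allow_stop && any(between == "*")) next
      all_matches[[length(all_matches) + 1L]] <- c(i, c2, h1, h2, g)
    }
  }
  if (!length(all_matches)) {
    return(data.frame(c1 = integer(0), c2 = integer(0), h1 = integer(0),
                      h2 = integer(0), cys_gap = integer(0)))
  }
  m <- do.call(rbind, all_matches)
  m <- m[order(m[, 1], m[, 5]), , drop = FALSE]
  sel <- list(); last_end <- 0L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) {
      sel[[length(sel) + 1L]] <- m[r, ]
      last_end <- m[r, 4]
    }
  }
  s <- do.call(rbind, sel)
  data.frame(c1 = s[, 1] - 1L, c2 = s[, 2] - 1L, h1 = s[, 3] - 1L,
             h2 = s[, 4] - 1L, cys_gap = s[, 5])
}

# Check every 4-mer directly against the default motif sets.
oracle_scan_motif <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  s1 <- c("Y", "C")
  s3 <- c("G", "A", "S", "T", "D", "N", "P", "E")
  s4 <- c("Q", "H")
  aa <- c(klfscout:::AA_STANDARD, "X")
  out <- integer(0)
  if (n < 4L) return(out)
  for (p in 1:(n - 3L)) {
    if (chars[p] %in% s1 && chars[p + 1L] %in% aa &&
        chars[p + 2L] %in% s3 && chars[p + 3L] %in% s4) {
      out <- c(out, p - 1L)
    }
  }
  out
}

# Maximal-run characterization: [i, j] is a run iff every consecutive spacing
# inside it is admissible and the spacings just outside are not.
oracle_tandem_runs <- function(starts, period = 14L, tol = 4L) {
  n <- length(starts)
  if (n < 2L) return(list())
  ok <- diff(starts) >= period - tol & diff(starts) <= period + tol
  runs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      inside <- all(ok[i:(j - 1L)])
      left_max <- i == 1L || !ok[i - 1L]
      right_max <- j == n || !ok[j]
      if (inside && left_max && right_max) {
        runs[[length(runs) + 1L]] <- i:j
      }
    }
  }
  runs
}

# Random protein over the 20 standard residues.
random_aa_seq <- function(n) {
  paste(sample(klfscout:::AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Build a consensus-like grammar string from explicit spacings using a neutral
# filler letter (no simulator involvement).
spaced_finger_protein <- function(cys_gaps, linker = 7L, lead = 5L,
                                  filler = "A", last = "H") {
  f <- vapply(seq_along(cys_gaps), function(k) {
    paste0("C", strrep(filler, cys_gaps[k]), "C", strrep(filler, 12L),
           "H", strrep(filler, 3L),
           if (k == length(cys_gaps)) last else "H")
  }, character(1))
  paste0(strrep(filler, lead), paste(f, collapse = strrep(filler, linker)),
         strrep(filler, lead))
}

# Peptide a frame hit should carry, re-derived from the DNA by Biostrings.
oracle_hit_peptide <- function(hit, dna) {
  sub <- substring(dna, hit$g_start + 1L, hit$g_end)
  if (hit$strand == "-") {
    sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  }
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}
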