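#' The N-terminal repeat motif pattern
#'
#' Per-position allowed residue sets for the four-residue repeat motif found in
#' the N-terminal regions of KLF18-like proteins: `[YC] x [GASTDNPE] [QH]`,
#' where `x` is any residue and the third-position set spells out the "small
#' residue or E" class.
#'
#' @param sets Optional list of four non-empty character vectors to override
#'   the default position sets.
#' @return A `motif_pattern` list of length 4.
#' @export
motif_pattern <- function(sets = NULL) {
  if (is.null(sets)) {
    sets <- list(c("Y", "C"),
                 c(AA_STANDARD, "X"),
                 c("G", "A", "S", "T", "D", "N", "P", "E"),
                 c("Q", "H"))
  }
  stopifnot(is.list(sets), length(sets) == 4L,
            all(vapply(sets, length, integer(1)) > 0L))
  structure(sets, class = "motif_pattern")
}

#' Scan a protein for the repeat motif
#'
#' Reports every match position, ascending. For the default pattern overlapping
#' matches are impossible (position sets 2-4 exclude Y and C... position 1
#' requires them), so all-position and non-overlapping counts coincide.
#'
#' @param protein A [protein_record()] or character sequence.
#' @param pattern A [motif_pattern()].
#' @return data.frame with `protein_id`, `start` (0-based), `matched_text`.
#' @examples
#' scan_motif("YAGQ")
#' @export
scan_motif <- function(protein, pattern = motif_pattern()) {
  seq <- as_sequence(protein)
  id <- protein_id(protein)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 4L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE))
  }
  ok <- lapply(pattern, function(set) chars %in% set)
  idx <- which(ok[[1]][1:(n - 3L)] & ok[[2]][2:(n - 2L)] &
               ok[[3]][3:(n - 1L)] & ok[[4]][4:n])
  data.frame(protein_id = rep(id, length(idx)),
             start = as.integer(idx - 1L),
             matched_text = if (length(idx)) substring(seq, idx, idx + 3L) else character(0),
             stringsAsFactors = FALSE)
}

#' Motif density
#'
#' Number of motif matches divided by protein length.
#'
#' @param hits Hit table from [scan_motif()].
#' @param protein_length Positive integer.
#' @return Numeric scalar.
#' @export
motif_density <- function(hits, protein_length) {
  if (!is.numeric(protein_length) || protein_length <= 0) {
    stop("protein_length must be positive")
  }
  nrow(hits) / protein_length
}

#' Extend motif hits to fixed-width segments
#'
#' Each four-residue hit with at least `flank` residues on both sides is
#' extended by `flank` residues N- and C-terminally, yielding
#' `flank + 4 + flank`-residue windows (14 by default). Boundary-truncated
#' hits are dropped, not padded, so all segments have equal width.
#'
#' @param hits Hit table from [scan_motif()].
#' @param protein The protein the hits came from.
#' @param flank Residues to add on each side (default 5).
#' @return Character vector of segments.
#' @export
extend_segments <- function(hits, protein, flank = 5L) {
  stopifnot(flank >= 0L)
  seq <- as_sequence(protein)
  n <- nchar(seq)
  keep <- hits$start >= flank & (hits$start + 4L + flank) <= n
  starts <- hits$start[keep] - flank + 1L            # to 1-based
  if (!length(starts)) return(character(0))
  substring(seq, starts, starts + 2L * flank + 3L)
}

#' Position-frequency matrix of repeat segments
#'
#' Counts residues per position over equal-length segments (`X` excluded from
#' counts), with per-position relative frequencies and information content in
#' bits (`log2(20)` minus the Shannon entropy of the position) — the numeric
#' substrate of a sequence logo.
#'
#' @param segments Character vector of equal-length segments.
#' @return A `repeat_pfm` list: `counts` (positions x 20 residues), `freq`,
#'   `info` (bits per position), `n_segments`, `width`.
#' @export
build_pfm <- function(segments) {
  if (!length(segments)) stop("no segments")
  w <- unique(nchar(segments))
  if (length(w) != 1L) stop("segments have mixed lengths")
  mat <- do.call(rbind, strsplit(segments, ""))
  counts <- t(apply(mat, 2, function(col) {
    col <- col[col %in% AA_STANDARD]
    table(factor(col, levels = AA_STANDARD))
  }))
  counts <- matrix(as.integer(counts), nrow = w,
                   dimnames = list(paste0("pos", seq_len(w)), AA_STANDARD))
  freq <- counts / pmax(rowSums(counts), 1L)
  info <- apply(freq, 1, function(p) {
    p <- p[p > 0]
    log2(20) - (-sum(p * log2(p)))
  })
  structure(list(counts = counts, freq = freq, info = info,
                 n_segments = length(segments), width = w),
            class = "repeat_pfm")
}

#' @export
print.repeat_pfm <- function(x, ...) {
  cat(sprintf("<repeat_pfm> %d segments x %d positions; total information %.2f bits\n",
              x$n_segments, x$width, sum(x$info)))
  invisible(x)
}

#' Detect tandem runs of motif hits
#'
#' Maximal chains of consecutive hits whose successive start differences fall
#' within `period_target` plus or minus `tolerance` — consecutive occurrences
#' of the 14-residue repeat unit.
#'
#' @param hits Hit table from [scan_motif()], starts ascending.
#' @param period_target Expected spacing between successive repeat starts
#'   (default 14).
#' @param tolerance Allowed deviation from the target (default 4).
#' @return List of runs; each run is a list with `indices` (row indices into
#'   `hits`), `starts`, and `periods` (successive start differences).
#' @export
find_tandem_runs <- function(hits, period_target = 14L, tolerance = 4L) {
  starts <- hits$start
  if (is.unsorted(starts)) stop("hits must be ascending")
  runs <- list()
  i <- 1L
  lo <- period_target - tolerance
  hi <- period_target + tolerance
  while (i <= length(starts)) {
    j <- i
    while (j < length(starts) && (starts[j + 1L] - starts[j]) >= lo &&
           (starts[j + 1L] - starts[j]) <= hi) {
      j <- j + 1L
    }
    if (j > i) {
      runs[[length(runs) + 1L]] <- list(indices = i:j, starts = starts[i:j],
                                        periods = diff(starts[i:j]))
    }
    i <- j + 1L
  }
  runs
}

#' Repeat profile of a protein
#'
#' Bundles the repeat-motif analytics for one protein: hit count, density,
#' extended segments, position-frequency matrix, and the fraction of hits
#' starting with tyrosine (KLF18-like) rather than cysteine (keratin-like).
#'
#' @inheritParams scan_motif
#' @param flank Flank width for segment extension (default 5).
#' @return A `repeat_profile` list.
#' @export
repeat_profile <- function(protein, pattern = motif_pattern(), flank = 5L) {
  seq <- as_sequence(protein)
  hits <- scan_motif(protein, pattern)
  segments <- extend_segments(hits, protein, flank)
  structure(list(protein_id = protein_id(protein),
                 n_hits = nrow(hits),
                 density = motif_density(hits, nchar(seq)),
                 segments = segments,
                 pfm = if (length(segments)) build_pfm(segments) else NULL,
                 y_fraction = if (nrow(hits)) {
                   mean(substring(hits$matched_text, 1L, 1L) == "Y")
                 } else NA_real_),
            class = "repeat_profile")
}

#' Rank a proteome by repeat-motif density
#'
#' @param proteins Named character vector of sequences or list of
#'   [protein_record()]s.
#' @param pattern A [motif_pattern()].
#' @return data.frame `(id, length, n_hits, density, y_fraction)` sorted by
#'   density descending, ties broken by id.
#' @export
rank_proteome <- function(proteins, pattern = motif_pattern()) {
  proteins <- as_protein_list(proteins)
  if (!length(proteins)) stop("empty proteome")
  rows <- lapply(proteins, function(p) {
    hits <- scan_motif(p, pattern)
    data.frame(id = p$id, length = nchar(p$sequence), n_hits = nrow(hits),
               density = motif_density(hits, nchar(p$sequence)),
               y_fraction = if (nrow(hits)) {
                 mean(substring(hits$matched_text, 1L, 1L) == "Y")
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$density, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
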