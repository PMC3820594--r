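#' Spacing-grammar parameters for C2H2 zinc-finger detection
#'
#' The SP/KLF family carries three C2H2 fingers with the spacing pattern
#' `C X(g) C X(12) H X(3) [H|C]`, where the cysteine-pair separation `g` is 4
#' for the first two fingers and 2 for the third, and successive fingers are
#' joined by 7-residue linkers. These constants parameterize the detector; the
#' defaults admit cysteine separations 2-4 so that both printed variants (and
#' intermediate ones) are matched and classified downstream.
#'
#' @param cys_gap_range Inclusive integer range for the separation between the
#'   two zinc-binding cysteines (default `c(2, 4)`).
#' @param inner_gap Residues strictly between the second cysteine and the first
#'   histidine (default 12).
#' @param his_gap Residues strictly between the two histidines (default 3).
#' @param linker_length Residues strictly between one finger's last histidine
#'   and the next finger's first cysteine in the canonical family signature
#'   (default 7); used for classification, not matching.
#' @param allow_terminal_cys_for_his Accept a cysteine in place of the final
#'   histidine (default `TRUE`); a C2H2 consensus allows either at the last
#'   zinc-binding position, as in the mouse candidate where the terminal
#'   histidine is replaced by a cysteine.
#' @return A `grammar_params` list.
#' @export
grammar_params <- function(cys_gap_range = c(2L, 4L),
                           inner_gap = 12L,
                           his_gap = 3L,
                           linker_length = 7L,
                           allow_terminal_cys_for_his = TRUE) {
  cys_gap_range <- as.integer(cys_gap_range)
  stopifnot(length(cys_gap_range) == 2L,
            cys_gap_range[1] >= 0L, cys_gap_range[1] <= cys_gap_range[2],
            inner_gap >= 0L, his_gap >= 0L, linker_length >= 0L,
            is.logical(allow_terminal_cys_for_his))
  structure(list(cys_gap_range = cys_gap_range,
                 inner_gap = as.integer(inner_gap),
                 his_gap = as.integer(his_gap),
                 linker_length = as.integer(linker_length),
                 allow_terminal_cys_for_his = isTRUE(allow_terminal_cys_for_his)),
            class = "grammar_params")
}

empty_fingers <- function() {
  data.frame(c1 = integer(0), c2 = integer(0), h1 = integer(0), h2 = integer(0),
             cys_gap = integer(0), inner_gap = integer(0), his_gap = integer(0))
}

#' Detect C2H2 zinc fingers by the spacing grammar
#'
#' Scans a protein left to right for non-overlapping fingers matching
#' `C X(cys_gap) C X(inner_gap) H X(his_gap) [H|C]`. Matching is greedy: a
#' matched finger consumes its residues, and within one start position the
#' smallest admissible cysteine separation is preferred. `X` (unknown residue)
#' matches any non-anchor position but never serves as a C/H anchor.
#'
#' @param protein A [protein_record()] or character sequence.
#' @param params A [grammar_params()] object.
#' @param allow_stop_in_spacer Treat `*` (stop, from translated DNA) like an
#'   unknown residue at non-anchor positions. Used by the translated genomic
#'   scan so that fingers disrupted by premature stop codons are still located
#'   and the stops reported; default `FALSE` for proteins.
#' @return A data.frame with one row per finger: 0-based residue indices
#'   `c1, c2, h1, h2` of the zinc-binding anchors, plus `cys_gap`, `inner_gap`,
#'   `his_gap` (residues strictly between the respective anchors), sorted by
#'   `c1`. Zero rows when nothing matches.
#' @examples
#' p <- paste0(strrep("A", 10), "C", "AAAA", "C", strrep("A", 12), "H", "AAA", "H")
#' find_c2h2_domains(p)
#' @export
find_c2h2_domains <- function(protein, params = grammar_params(),
                              allow_stop_in_spacer = FALSE) {
  seq <- as_sequence(protein)
  chars <- seq_chars(seq)
  n <- length(chars)
  spacer_ok <- function(from, to) { # 1-based inclusive, positions strictly between anchors
    if (to < from) return(TRUE)
    seg <- chars[from:to]
    allow_stop_in_spacer || !any(seg == "*")
  }
  out <- list()
  i <- 1L
  gaps <- params$cys_gap_range[1]:params$cys_gap_range[2]
  while (i <= n) {
    if (chars[i] != "C") { i <- i + 1L; next }
    matched <- FALSE
    for (g in gaps) {
      c2 <- i + g + 1L
      h1 <- c2 + params$inner_gap + 1L
      h2 <- h1 + params$his_gap + 1L
      if (h2 > n) break
      term_ok <- chars[h2] == "H" ||
        (params$allow_terminal_cys_for_his && chars[h2] == "C")
      if (chars[c2] == "C" && chars[h1] == "H" && term_ok &&
          spacer_ok(i + 1L, c2 - 1L) &&
          spacer_ok(c2 + 1L, h1 - 1L) &&
          spacer_ok(h1 + 1L, h2 - 1L)) {
        out[[length(out) + 1L]] <- c(i - 1L, c2 - 1L, h1 - 1L, h2 - 1L, g)
        i <- h2 + 1L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (!length(out)) return(empty_fingers())
  m <- do.call(rbind, out)
  data.frame(c1 = m[, 1], c2 = m[, 2], h1 = m[, 3], h2 = m[, 4],
             cys_gap = m[, 5],
             inner_gap = params$inner_gap, his_gap = params$his_gap)
}

#' Summarize a finger set into a family signature
#'
#' Computes the ordered cysteine-pair separations and inter-finger linker
#' lengths, and assigns a family label:
#' \describe{
#'   \item{SPKLF_STRICT}{three fingers, separations (4,4,2), canonical inner
#'     (12) and histidine (3) gaps, both linkers 7 — the SP/KLF consensus.}
#'   \item{SPKLF_RELAXED}{three fingers, linkers 7, canonical inner/his gaps,
#'     separations drawn from \{2,4\} other than (4,4,2) — e.g. the rat variant
#'     whose first-finger separation contracted from four to two residues.}
#'   \item{EGR_LIKE}{three fingers with separations (4,2,2).}
#'   \item{WT1_LIKE}{four fingers, the first three (4,4,2) and a fourth with
#'     separation 4 — the Wilms' tumor protein arrangement.}
#'   \item{OTHER_C2H2 / NO_C2H2}{anything else with / without fingers.}
#' }
#'
#' @param fingers Finger data.frame from [find_c2h2_domains()], sorted and
#'   non-overlapping.
#' @param protein_length Length of the parent protein (stored for reporting).
#' @return A `family_signature` list: `finger_count`, `cys_gaps`,
#'   `linker_lengths`, `label`, `protein_length`.
#' @export
signature_of <- function(fingers, protein_length = NA_integer_) {
  stopifnot(is.data.frame(fingers))
  n <- nrow(fingers)
  if (n > 1L) {
    if (is.unsorted(fingers$c1, strictly = TRUE)) stop("fingers must be sorted by c1")
    if (any(fingers$c1[-1] <= fingers$h2[-n])) stop("malformed input: overlapping fingers")
  }
  cys_gaps <- as.integer(fingers$cys_gap)
  linkers <- if (n >= 2L) as.integer(fingers$c1[-1] - fingers$h2[-n] - 1L) else integer(0)
  canonical <- n > 0L && all(fingers$inner_gap == 12L) && all(fingers$his_gap == 3L)
  label <- if (n == 0L) {
    "NO_C2H2"
  } else if (n == 3L && canonical) {
    if (identical(cys_gaps, c(4L, 4L, 2L)) && all(linkers == 7L)) {
      "SPKLF_STRICT"
    } else if (identical(cys_gaps, c(4L, 2L, 2L))) {
      "EGR_LIKE"
    } else if (all(cys_gaps %in% c(2L, 4L)) && all(linkers == 7L)) {
      "SPKLF_RELAXED"
    } else "OTHER_C2H2"
  } else if (n == 4L && canonical &&
             identical(cys_gaps[1:3], c(4L, 4L, 2L)) && cys_gaps[4] == 4L) {
    "WT1_LIKE"
  } else "OTHER_C2H2"
  structure(list(finger_count = n, cys_gaps = cys_gaps,
                 linker_lengths = linkers, label = label,
                 protein_length = as.integer(protein_length)),
            class = "family_signature")
}

#' @export
print.family_signature <- function(x, ...) {
  cat(sprintf("<family_signature> %s: %d finger(s), cys gaps (%s), linkers (%s)\n",
              x$label, x$finger_count, paste(x$cys_gaps, collapse = ","),
              paste(x$linker_lengths, collapse = ",")))
  invisible(x)
}

#' Classify a protein's SP/KLF membership
#'
#' Convenience wrapper: [find_c2h2_domains()] then [signature_of()].
#'
#' @inheritParams find_c2h2_domains
#' @return A `family_signature`.
#' @export
classify_protein <- function(protein, params = grammar_params()) {
  seq <- as_sequence(protein)
  signature_of(find_c2h2_domains(seq, params), nchar(seq))
}

#' DNA-contact residue specification
#'
#' Offsets, within the 12-residue spacer between the second cysteine and the
#' first histidine of each finger, expected to hold the conserved DNA-contact
#' residues of the SP/KLF family: three invariant arginines (two in finger 2,
#' one in finger 3) that hydrogen-bond guanine bases of the GC/GT box, and
#' three acidic partners (two aspartates and one glutamate) that orient their
#' guanidinium groups. Default offsets follow canonical C2H2
#' recognition-helix geometry, where helix positions -1, +2, +3 and +6 map to
#' spacer offsets 5, 7, 8 and 11; they are configuration, not fixed truth.
#'
#' @param finger Integer vector of finger indices (1-based) per entry.
#' @param offset Integer vector of 0-based offsets into the inner spacer.
#' @param class Expected residue class per entry: `"R"` (arginine) or `"DE"`
#'   (aspartate/glutamate).
#' @param inner_gap Spacer width the offsets must fall inside (default 12).
#' @return A `contact_spec` data.frame.
#' @export
contact_spec <- function(finger = c(2L, 2L, 3L, 2L, 2L, 3L),
                         offset = c(5L, 11L, 5L, 7L, 8L, 7L),
                         class = c("R", "R", "R", "DE", "DE", "DE"),
                         inner_gap = 12L) {
  stopifnot(length(finger) == length(offset), length(offset) == length(class),
            all(class %in% c("R", "DE")),
            all(offset >= 0L), all(offset < inner_gap))
  structure(data.frame(finger = as.integer(finger), offset = as.integer(offset),
                       class = class, stringsAsFactors = FALSE),
            class = c("contact_spec", "data.frame"))
}

#' Report conservation of DNA-contact residues
#'
#' For each entry of the contact specification, reads the residue at
#' `c2 + 1 + offset` of the named finger and flags whether it matches the
#' expected class (R, or D/E).
#'
#' @param protein A [protein_record()] or character sequence.
#' @param fingers Exactly three fingers from [find_c2h2_domains()].
#' @param spec A [contact_spec()].
#' @return A `conservation_report` list: `checks` (data.frame with `finger`,
#'   `offset`, `expected`, `observed`, `pass`), `n_pass`, `n_checked`.
#' @export
contact_report <- function(protein, fingers, spec = contact_spec()) {
  if (nrow(fingers) != 3L) {
    stop("not applicable: contact report requires exactly 3 fingers, got ",
         nrow(fingers))
  }
  seq <- as_sequence(protein)
  pos0 <- fingers$c2[spec$finger] + 1L + spec$offset      # 0-based residue index
  observed <- substring(seq, pos0 + 1L, pos0 + 1L)
  pass <- ifelse(spec$class == "R", observed == "R", observed %in% c("D", "E"))
  checks <- data.frame(finger = spec$finger, offset = spec$offset,
                       expected = spec$class, observed = observed, pass = pass,
                       stringsAsFactors = FALSE)
  structure(list(checks = checks, n_pass = sum(pass), n_checked = nrow(checks)),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %d/%d contact residues conserved\n",
              x$n_pass, x$n_checked))
  print(x$checks)
  invisible(x)
}

#' Extract the zinc-finger region of a protein
#'
#' Substring from the first finger's first cysteine to the last finger's final
#' zinc-binding residue, inclusive.
#'
#' @inheritParams contact_report
#' @return Amino-acid string.
#' @export
extract_zf_region <- function(protein, fingers) {
  if (nrow(fingers) < 1L) stop("not applicable: no fingers")
  seq <- as_sequence(protein)
  substring(seq, fingers$c1[1] + 1L, fingers$h2[nrow(fingers)] + 1L)
}

#' Tabulate finger signatures for a set of proteins
#'
#' Produces the per-protein report written by the proteome-scan stage: finger
#' coordinates (1-based inclusive for readability), cysteine separations,
#' family label, and contact-residue pass fraction where applicable.
#'
#' @param proteins Named character vector of sequences or list of
#'   [protein_record()]s.
#' @param params A [grammar_params()].
#' @param spec A [contact_spec()].
#' @return A data.frame with one row per protein.
#' @export
signature_table <- function(proteins, params = grammar_params(),
                            spec = contact_spec()) {
  proteins <- as_protein_list(proteins)
  rows <- lapply(proteins, function(p) {
    f <- find_c2h2_domains(p, params)
    sig <- signature_of(f, nchar(p$sequence))
    frac <- NA_real_
    if (nrow(f) == 3L) {
      cr <- contact_report(p, f, spec)
      frac <- cr$n_pass / cr$n_checked
    }
    data.frame(id = p$id,
               finger_count = sig$finger_count,
               finger_coords = paste(sprintf("%d-%d", f$c1 + 1L, f$h2 + 1L),
                                     collapse = ";"),
               cys_gaps = paste(sig$cys_gaps, collapse = ","),
               label = sig$label,
               contact_pass_fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Coerce a proteome argument (named character vector, list of records, or a
## single record) to a list of protein_records.
as_protein_list <- function(proteins) {
  if (inherits(proteins, "protein_record")) return(list(proteins))
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- sprintf("protein_%d", seq_along(proteins))
    return(mapply(protein_record, ids, proteins, SIMPLIFY = FALSE))
  }
  if (is.list(proteins)) {
    stopifnot(all(vapply(proteins, inherits, logical(1), "protein_record")))
    return(proteins)
  }
  stop("cannot interpret `proteins`")
}
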