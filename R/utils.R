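#' klfscout: discovery of SP/KLF-family zinc-finger genes and pseudogenes
#'
#' End-to-end tooling for finding new SP/KLF-family members in genomic
#' sequence: a C2H2 spacing-grammar detector and classifier, N-terminal
#' repeat-motif analytics, synteny-anchored locus finding, six-frame
#' translated scanning with pseudogene calling, duplication-history
#' inference, and a synthetic-genome simulator with planted truth.
#'
#' @keywords internal
"_PACKAGE"

## The 20 standard amino acids, alphabetical one-letter codes.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_STANDARD <- c("A", "C", "G", "T")

## Residues used for unconstrained simulator filler. Cysteine and histidine
## are excluded so filler can never complete a zinc-finger grammar match, and
## tyrosine so it can never open a repeat-motif match; both exclusions are
## load-bearing for the planted-truth guarantees and are exercised by tests.
FILLER_AA <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
               "R", "S", "T", "V", "W")

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic per-stage sub-seed derived from a master seed and a tag,
## kept below 2^31 so it is a valid R integer.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483563)
}

#' Create a protein record
#'
#' A named protein sequence with a provenance tag. The sequence is normalized:
#' upper-cased, whitespace stripped, and any letter outside the 20 standard
#' amino acids mapped to `X`.
#'
#' @param id Character scalar identifier.
#' @param sequence Amino-acid string.
#' @param source_tag Optional provenance label (e.g. genome or species).
#' @return A `protein_record` list with elements `id`, `sequence`, `source_tag`.
#' @examples
#' protein_record("p1", "mkl vYA")$sequence
#' @export
protein_record <- function(id, sequence, source_tag = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_protein(sequence)
  if (!nzchar(seq)) stop("protein sequence must be non-empty")
  structure(list(id = id, sequence = seq, source_tag = source_tag),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa%s)\n", x$id, nchar(x$sequence),
              if (is.na(x$source_tag)) "" else paste0(", ", x$source_tag)))
  invisible(x)
}

normalize_protein <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- toupper(gsub("[[:space:]]+", "", sequence))
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% c(AA_STANDARD, "X", "*"))
  chars[bad] <- "X"
  paste(chars, collapse = "")
}

## Accept a protein_record or a bare character sequence.
as_sequence <- function(protein) {
  if (inherits(protein, "protein_record")) return(protein$sequence)
  if (is.character(protein) && length(protein) == 1L) return(normalize_protein(protein))
  stop("expected a protein_record or a single character sequence")
}

protein_id <- function(protein, default = NA_character_) {
  if (inherits(protein, "protein_record")) protein$id else default
}

seq_chars <- function(seq) strsplit(seq, "")[[1]]

## md5 digest of an in-memory character blob (via a temp file; tools has no
## string digest).
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
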