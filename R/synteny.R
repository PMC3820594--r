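#' Default anchor genes flanking the KLF17/KLF18 locus
#'
#' In placental mammals the KLF17/KLF18 pair is sandwiched by three upstream
#' genes (B4GALT2, CCDC24, SLC6A9) and three downstream genes (DMAP1, ERI3,
#' RNF220) in conserved order; one found anchor per side suffices to define a
#' locus, additional anchors raise confidence.
#'
#' @return list with `upstream` and `downstream` character vectors.
#' @export
klf_anchor_genes <- function() {
  list(upstream = c("B4GALT2", "CCDC24", "SLC6A9"),
       downstream = c("DMAP1", "ERI3", "RNF220"))
}

#' Build a gene table
#'
#' A per-genome annotation table. Intervals are 0-based half-open; strand is
#' `+` or `-`; gene ids must be unique within a genome.
#'
#' @param genome_id Character scalar.
#' @param features data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return A `gene_table` list with features sorted by chromosome and start.
#' @export
gene_table <- function(genome_id, features) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L,
            is.data.frame(features),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(features)))
  if (anyDuplicated(features$gene_id)) stop("duplicate gene_id within a genome")
  if (any(features$start >= features$end)) stop("gene intervals must satisfy start < end")
  if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(genome_id = genome_id, features = features), class = "gene_table")
}

#' Locate a locus by flanking anchor genes
#'
#' Searches each chromosome for at least one upstream and one downstream anchor
#' in consistent order and returns the interval between the innermost found
#' anchors. Orientation is normalized: a locus carried on a chromosome in
#' mirrored orientation (downstream anchors preceding upstream ones) is
#' recognized and reported with `orientation = "reflected"`.
#'
#' @param table A [gene_table()].
#' @param upstream,downstream Non-empty character vectors of anchor gene ids.
#' @param max_span Maximum admissible interval width in bp (default 1e6);
#'   wider candidate intervals are rejected as spurious.
#' @return A `synteny_locus` list (`genome_id`, `chrom`, `start`, `end`,
#'   `orientation`, `upstream_found`, `downstream_found`) when a locus is
#'   found; otherwise a `synteny_absent` object whose `diagnostic` field
#'   explains why (e.g. anchors split across chromosomes). Test with
#'   [locus_found()].
#' @export
find_anchored_interval <- function(table,
                                   upstream = klf_anchor_genes()$upstream,
                                   downstream = klf_anchor_genes()$downstream,
                                   max_span = 1e6) {
  stopifnot(inherits(table, "gene_table"), length(upstream) > 0L, length(downstream) > 0L)
  feats <- table$features
  candidates <- list()
  diagnostics <- character(0)
  for (chrom in unique(feats$chrom)) {
    f <- feats[feats$chrom == chrom, , drop = FALSE]
    up <- f[f$gene_id %in% upstream, , drop = FALSE]
    dn <- f[f$gene_id %in% downstream, , drop = FALSE]
    if (!nrow(up) || !nrow(dn)) next
    if (max(up$end) <= min(dn$start)) {
      orientation <- "forward"
      start <- max(up$end); end <- min(dn$start)
      up_found <- up$gene_id[order(up$start)]
      dn_found <- dn$gene_id[order(dn$start)]
    } else if (max(dn$end) <= min(up$start)) {
      orientation <- "reflected"
      start <- max(dn$end); end <- min(up$start)
      up_found <- up$gene_id[order(-up$start)]
      dn_found <- dn$gene_id[order(-dn$start)]
    } else {
      diagnostics <- c(diagnostics,
                       sprintf("%s: anchors interleave, ordering inconsistent", chrom))
      next
    }
    if (end - start > max_span) {
      diagnostics <- c(diagnostics,
                       sprintf("%s: interval span %d exceeds max_span", chrom, end - start))
      next
    }
    candidates[[chrom]] <- structure(
      list(genome_id = table$genome_id, chrom = chrom,
           start = start, end = end, orientation = orientation,
           upstream_found = up_found, downstream_found = dn_found),
      class = "synteny_locus")
  }
  if (!length(candidates)) {
    has_up <- any(feats$gene_id %in% upstream)
    has_dn <- any(feats$gene_id %in% downstream)
    if (has_up && has_dn && !length(diagnostics)) {
      diagnostics <- "anchors split across chromosomes"
    } else if (!has_up || !has_dn) {
      diagnostics <- c(diagnostics, "one or both anchor sides missing")
    }
    return(structure(list(genome_id = table$genome_id,
                          diagnostic = paste(diagnostics, collapse = "; ")),
                     class = "synteny_absent"))
  }
  n_anchors <- vapply(candidates, function(x) {
    length(x$upstream_found) + length(x$downstream_found)
  }, integer(1))
  best <- names(sort(n_anchors, decreasing = TRUE))
  best <- best[order(-n_anchors[best], best)][1]
  candidates[[best]]
}

#' Did anchored-locus finding succeed?
#'
#' @param locus Return value of [find_anchored_interval()].
#' @return Logical.
#' @export
locus_found <- function(locus) inherits(locus, "synteny_locus")

#' @export
print.synteny_absent <- function(x, ...) {
  cat(sprintf("<synteny_absent> %s: %s\n", x$genome_id, x$diagnostic))
  invisible(x)
}

#' @export
print.synteny_locus <- function(x, ...) {
  cat(sprintf("<synteny_locus> %s %s:%d-%d (%s), anchors %s | %s\n",
              x$genome_id, x$chrom, x$start, x$end, x$orientation,
              paste(x$upstream_found, collapse = ","),
              paste(x$downstream_found, collapse = ",")))
  invisible(x)
}

#' Relative orientation of two neighboring genes
#'
#' For two non-overlapping genes on one chromosome (sorted internally so the
#' leftmost is first): `tail_to_tail` when they are transcribed toward each
#' other (`+` then `-`), `head_to_head` when transcribed apart (`-` then `+`),
#' `co_oriented` otherwise.
#'
#' @param a,b Lists or one-row data.frames with `start`, `end`, `strand`.
#' @return One of `"tail_to_tail"`, `"head_to_head"`, `"co_oriented"`.
#' @export
orientation_relation <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  if (a$end > b$start) stop("genes overlap; orientation relation undefined")
  if (a$strand == "+" && b$strand == "-") return("tail_to_tail")
  if (a$strand == "-" && b$strand == "+") return("head_to_head")
  "co_oriented"
}

#' Count candidate gene copies fully inside a locus
#'
#' @param locus A `synteny_locus`.
#' @param candidate_hits data.frame of features (`chrom`, `start`, `end`).
#' @return Integer count of hits contained in the locus interval; hits
#'   straddling a boundary are excluded.
#' @export
count_copies_in_interval <- function(locus, candidate_hits) {
  if (!locus_found(locus)) return(0L)
  if (!nrow(candidate_hits)) return(0L)
  sum(candidate_hits$chrom == locus$chrom &
      candidate_hits$start >= locus$start &
      candidate_hits$end <= locus$end)
}

#' Cross-genome presence / copy-number matrix
#'
#' Combines per-genome locus and scan results into the survey matrix: whether
#' the anchored locus was found, how many gene/pseudogene copies it holds, and
#' a genome-level status. Status precedence: `coding` if any copy is coding,
#' else `pseudogene` if any copy is a pseudogene, else `partial` when no
#' finger-coding copy was detected but the interval shows repeat-region
#' similarity (the N-terminal repeat signal seen in low-coverage genomes),
#' else `absent`.
#'
#' @param results List of per-genome lists with elements `genome_id`,
#'   `locus_found` (logical), `statuses` (character vector, one per scanned
#'   copy: `"coding"`/`"pseudogene"`/`"absent"`), and `repeat_region_found`
#'   (logical).
#' @return data.frame with columns `genome_id`, `locus_found`, `n_copies`,
#'   `status`.
#' @export
build_presence_matrix <- function(results) {
  rows <- lapply(results, function(r) {
    statuses <- r$statuses %||% character(0)
    n_copies <- sum(statuses %in% c("coding", "pseudogene"))
    status <- if (any(statuses == "coding")) "coding"
      else if (any(statuses == "pseudogene")) "pseudogene"
      else if (isTRUE(r$repeat_region_found)) "partial"
      else "absent"
    data.frame(genome_id = r$genome_id,
               locus_found = isTRUE(r$locus_found),
               n_copies = n_copies, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$n_copies[out$status == "absent"] == 0L))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
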