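#' Translate a DNA sequence in all six frames
#'
#' Standard genetic code; stop codons translate to `*`; codons containing `N`
#' (or other ambiguity letters) translate to `X`, which never serves as a C/H
#' anchor downstream, so assembly-gap masking yields partial rather than false
#' fingers. Trailing partial codons are dropped.
#'
#' @param dna DNA string over `A,C,G,T,N`.
#' @return List of six lists with `strand` (`+`/`-`), `frame` (0-2), `peptide`.
#' @export
translate_six_frames <- function(dna) {
  dna <- toupper(dna)
  L <- nchar(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else reverse_complement(dna)
    sobj <- Biostrings::DNAString(s)
    for (f in 0:2) {
      nc <- (L - f) %/% 3L
      pep <- if (nc < 1L) "" else as.character(Biostrings::translate(
        Biostrings::subseq(sobj, start = f + 1L, width = 3L * nc),
        if.fuzzy.codon = "X"))
      out[[length(out) + 1L]] <- list(strand = strand, frame = f, peptide = pep)
    }
  }
  out
}

## Map an amino-acid interval [a1, a2] (0-based, inclusive) of a frame
## translation back to genomic coordinates (0-based half-open) of the input
## sequence of length L.
aa_to_genomic <- function(a1, a2, frame, strand, L) {
  d1 <- frame + 3L * a1
  d2 <- frame + 3L * (a2 + 1L)
  if (strand == "+") c(d1, d2) else c(L - d2, L - d1)
}

#' Six-frame translated scan for zinc-finger-coding regions
#'
#' Translates all six frames, runs the spacing-grammar detector on each
#' translation (tolerating in-frame stops inside spacers so that pseudogenized
#' fingers are still located and their stops reported), groups neighboring
#' fingers of one frame into fragments, and maps every fragment back to exact
#' genomic coordinates.
#'
#' @param dna DNA string.
#' @param params A [grammar_params()].
#' @param chrom Optional chromosome label carried into the hits.
#' @param max_group_linker Fingers in one frame separated by at most this many
#'   residues are grouped into one fragment (default 15; the canonical linker
#'   is 7).
#' @return List of `frame_hit` lists sorted by genomic start: `chrom`,
#'   `strand`, `frame`, `g_start`, `g_end` (0-based half-open), `peptide`
#'   (fragment translation), `fingers` (coordinates local to the fragment),
#'   `n_fingers`, `stop_aa` (0-based fragment offsets of in-frame stops),
#'   `stop_genomic` (codon start positions of those stops).
#' @export
six_frame_scan <- function(dna, params = grammar_params(), chrom = NA_character_,
                           max_group_linker = 15L) {
  L <- nchar(dna)
  hits <- list()
  for (tr in translate_six_frames(dna)) {
    if (!nzchar(tr$peptide)) next
    fingers <- find_c2h2_domains(tr$peptide, params, allow_stop_in_spacer = TRUE)
    if (!nrow(fingers)) next
    ## group consecutive fingers joined by short linkers into fragments
    grp <- cumsum(c(1L, (fingers$c1[-1] - fingers$h2[-nrow(fingers)] - 1L) > max_group_linker))
    for (g in unique(grp)) {
      fg <- fingers[grp == g, , drop = FALSE]
      a1 <- fg$c1[1]; a2 <- fg$h2[nrow(fg)]
      gcoords <- aa_to_genomic(a1, a2, tr$frame, tr$strand, L)
      peptide <- substring(tr$peptide, a1 + 1L, a2 + 1L)
      local <- fg
      for (col in c("c1", "c2", "h1", "h2")) local[[col]] <- local[[col]] - a1
      stop_aa <- which(seq_chars(peptide) == "*") - 1L
      stop_genomic <- vapply(stop_aa, function(a) {
        aa_to_genomic(a1 + a, a1 + a, tr$frame, tr$strand, L)[1]
      }, numeric(1))
      hits[[length(hits) + 1L]] <- structure(
        list(chrom = chrom, strand = tr$strand, frame = tr$frame,
             g_start = gcoords[1], g_end = gcoords[2],
             peptide = peptide, fingers = local, n_fingers = nrow(fg),
             stop_aa = as.integer(stop_aa), stop_genomic = stop_genomic),
        class = "frame_hit")
    }
  }
  hits[order(vapply(hits, `[[`, numeric(1), "g_start"))]
}

## Is there a GT..AG sub-interval of `gap_dna` whose excision leaves a number
## of coding bases divisible by 3 and at most `max_linker` codons? Among
## consistent pairs, the one whose spliced linker is closest to the canonical
## `preferred_linker` codons is chosen (ties: smallest donor offset, then
## widest intron). Returns the 0-based [start, end) intron interval, or NULL.
## Used both by gene-model assembly and by the simulator's negative-control
## generator.
find_consistent_splice <- function(gap_dna, max_linker = 12L,
                                   preferred_linker = 7L) {
  Lg <- nchar(gap_dna)
  if (Lg < 4L) return(NULL)
  chars <- seq_chars(toupper(gap_dna))
  gt <- which(chars[-Lg] == "G" & chars[-1] == "T")            # donor offset, 1-based
  ag <- which(chars[-Lg] == "A" & chars[-1] == "G") + 1L       # acceptor end, 1-based
  best <- NULL; best_key <- NULL
  for (g in gt) {
    for (e in ag) {
      if (e <= g + 1L) next
      coding <- (g - 1L) + (Lg - e)
      if (coding %% 3L != 0L || coding %/% 3L > max_linker) next
      key <- c(abs(coding %/% 3L - preferred_linker), g, -(e - g))
      if (is.null(best_key) ||
          key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] && key[3] < best_key[3])) {
        best <- c(g - 1L, e); best_key <- key
      }
    }
  }
  best
}

#' Assemble a gene model from frame hits
#'
#' A single fragment covering three or more fingers yields an intronless
#' single-segment model. A one-finger fragment and a two-finger fragment on the
#' same strand within `pair_window` bp are tested for a canonical GT..AG intron
#' between them: the inter-fragment gap must contain a GT..AG sub-interval
#' whose removal leaves an in-frame linker of plausible length (finger-coding
#' fragments end at codon boundaries, so linker codons flank the intron).
#' Splice-consistent pairs give an `intron_containing` two-segment model;
#' anything else is `unknown`.
#'
#' @param hits List of `frame_hit`s from [six_frame_scan()] for one locus.
#' @param dna The scanned DNA (needed to inspect inter-fragment gaps).
#' @param pair_window Maximum distance in bp between paired fragments
#'   (default 20000).
#' @return A `locus_model` list: `segments` (frame hits in coding order),
#'   `strand`, `intron_structure` (`intron_containing` / `intronless` /
#'   `unknown`), `intron` (genomic interval or `NULL`), `premature_stops`
#'   (genomic codon starts of in-frame stops inside finger-coding segments),
#'   `total_fingers`.
#' @export
assemble_gene_model <- function(hits, dna, pair_window = 20000L) {
  if (!length(hits)) {
    return(structure(list(segments = list(), strand = NA_character_,
                          intron_structure = "unknown", intron = NULL,
                          premature_stops = numeric(0), total_fingers = 0L),
                     class = "locus_model"))
  }
  ## keep the strand carrying the most fingers (ties resolved to '+')
  strands <- vapply(hits, `[[`, character(1), "strand")
  nf <- vapply(hits, `[[`, integer(1), "n_fingers")
  per_strand <- tapply(nf, strands, sum)
  strand <- names(per_strand)[order(-per_strand, names(per_strand))][1]
  hits <- hits[strands == strand]

  full <- hits[vapply(hits, function(h) h$n_fingers >= 3L, logical(1))]
  if (length(full) >= 2L) {
    stop("conflicting overlapping hits: ",
         paste(vapply(full, function(h) sprintf("%s:%d-%d", h$strand, h$g_start, h$g_end),
                      character(1)), collapse = ", "))
  }
  if (length(full) == 1L) {
    seg <- full[[1]]
    return(structure(list(segments = list(seg), strand = strand,
                          intron_structure = "intronless", intron = NULL,
                          premature_stops = seg$stop_genomic,
                          total_fingers = seg$n_fingers),
                     class = "locus_model"))
  }

  f1s <- hits[nf[strands == strand] == 1L]
  f23s <- hits[nf[strands == strand] == 2L]
  best <- NULL
  for (h1 in f1s) {
    for (h2 in f23s) {
      upstream_first <- if (strand == "+") h1$g_end <= h2$g_start else h2$g_end <= h1$g_start
      if (!upstream_first) next
      gap_iv <- if (strand == "+") c(h1$g_end, h2$g_start) else c(h2$g_end, h1$g_start)
      gap_bp <- gap_iv[2] - gap_iv[1]
      if (gap_bp > pair_window) next
      gap_dna <- substring(dna, gap_iv[1] + 1L, gap_iv[2])
      if (strand == "-") gap_dna <- reverse_complement(gap_dna)
      splice <- find_consistent_splice(gap_dna)
      cand <- list(h1 = h1, h2 = h2, gap_iv = gap_iv, gap_bp = gap_bp, splice = splice)
      better <- is.null(best) ||
        (!is.null(splice) && is.null(best$splice)) ||
        (is.null(splice) == is.null(best$splice) && gap_bp < best$gap_bp)
      if (better) best <- cand
    }
  }
  if (!is.null(best)) {
    segs <- list(best$h1, best$h2)
    intron <- NULL
    structure_lab <- "unknown"
    if (!is.null(best$splice)) {
      structure_lab <- "intron_containing"
      intron <- if (best$h1$strand == "+") {
        best$gap_iv[1] + best$splice
      } else {
        c(best$gap_iv[2] - best$splice[2], best$gap_iv[2] - best$splice[1])
      }
    }
    return(structure(list(segments = segs, strand = strand,
                          intron_structure = structure_lab, intron = intron,
                          premature_stops = c(best$h1$stop_genomic, best$h2$stop_genomic),
                          total_fingers = best$h1$n_fingers + best$h2$n_fingers),
                     class = "locus_model"))
  }
  ## no pairing possible: keep all fragments, structure unknown
  ord <- order(vapply(hits, `[[`, numeric(1), "g_start"))
  if (strand == "-") ord <- rev(ord)
  hits <- hits[ord]
  structure(list(segments = hits, strand = strand,
                 intron_structure = "unknown", intron = NULL,
                 premature_stops = unlist(lapply(hits, `[[`, "stop_genomic")),
                 total_fingers = sum(vapply(hits, `[[`, integer(1), "n_fingers"))),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %d segment(s), %d finger(s), %s, %d premature stop(s) -> %s\n",
              length(x$segments), x$total_fingers, x$intron_structure,
              length(x$premature_stops), call_status(x)))
  invisible(x)
}

#' Reconstruct the finger-region peptide of a locus model
#'
#' For an intronless model this is the single fragment's translation. For an
#' intron-containing model the spliced linker is restored: the coding bases of
#' the inter-fragment gap (gap minus intron, in coding orientation) are
#' translated and inserted between the two fragment peptides. For other
#' models the fragment peptides are concatenated as-is. In-frame stops are
#' reported as `X` so the peptide is a valid amino-acid string.
#'
#' @param model A `locus_model`.
#' @param dna The DNA the model's coordinates refer to.
#' @return Amino-acid string (empty for an absent model).
#' @export
model_peptide <- function(model, dna) {
  stopifnot(inherits(model, "locus_model"))
  if (!length(model$segments)) return("")
  peps <- vapply(model$segments, `[[`, character(1), "peptide")
  if (model$intron_structure == "intron_containing" && length(model$segments) == 2L) {
    s1 <- model$segments[[1]]; s2 <- model$segments[[2]]
    i1 <- model$intron[1]; i2 <- model$intron[2]
    linker_dna <- if (model$strand == "+") {
      paste0(substring(dna, s1$g_end + 1L, i1), substring(dna, i2 + 1L, s2$g_start))
    } else {
      paste0(reverse_complement(substring(dna, i2 + 1L, s1$g_start)),
             reverse_complement(substring(dna, s2$g_end + 1L, i1)))
    }
    linker <- if (nzchar(linker_dna)) {
      as.character(Biostrings::translate(Biostrings::DNAString(linker_dna),
                                         if.fuzzy.codon = "X"))
    } else ""
    return(gsub("\\*", "X", paste0(peps[1], linker, peps[2])))
  }
  gsub("\\*", "X", paste(peps, collapse = ""))
}

#' Call coding / pseudogene / absent status of a locus model
#'
#' A locus is a pseudogene when an in-frame premature stop codon lies inside a
#' finger-coding segment, or when the finger set is deteriorated (fewer than
#' three fingers recovered, i.e. a zinc-binding anchor has been lost); coding
#' when three clean fingers are present; absent when nothing was found.
#'
#' @param model A `locus_model` from [assemble_gene_model()].
#' @return One of `"coding"`, `"pseudogene"`, `"absent"`.
#' @export
call_status <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  if (!length(model$segments)) return("absent")
  if (length(model$premature_stops) > 0L) return("pseudogene")
  if (model$total_fingers < 3L) return("pseudogene")
  "coding"
}

#' Detect N-terminal repeat-region similarity in DNA
#'
#' Looks for a tandem run of the repeat motif in any of the six frame
#' translations — the signature used to flag loci whose finger-coding DNA is
#' missing or masked but whose N-terminal repeat region is still recognizable
#' (`partial` status in the presence matrix). Isolated chance motif matches in
#' random sequence do not form 14-residue-periodic runs, so a short run is
#' already specific.
#'
#' @param dna DNA string.
#' @param pattern A [motif_pattern()].
#' @param min_run Minimum tandem-run length (default 3 consecutive units).
#' @return Logical.
#' @export
detect_repeat_region <- function(dna, pattern = motif_pattern(), min_run = 3L) {
  for (tr in translate_six_frames(dna)) {
    if (!nzchar(tr$peptide)) next
    hits <- scan_motif(tr$peptide, pattern)
    if (nrow(hits) < min_run) next
    runs <- find_tandem_runs(hits)
    if (any(vapply(runs, function(r) length(r$indices), integer(1)) >= min_run)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Scan an interval for gene copies
#'
#' Runs the six-frame scan and resolves the fragments into gene copies per
#' strand in three stages: (1) one-finger and two-finger fragments joined by a
#' splice-consistent GT..AG gap become two-exon copies (greedy by gap, each
#' fragment used once); (2) fragments already carrying a full three-finger
#' complement become single-exon copies; (3) remaining fragments are clustered
#' by genomic proximity, and clusters with at least `min_leftover_fingers`
#' fingers become copies with unknown intron structure (e.g. deteriorated
#' pseudogenes or non-canonically spliced loci). Isolated single-finger
#' matches — the chance background of a six-frame scan — are discarded, and
#' only stop-free fragments count toward the leftover evidence threshold
#' (the stop-tolerant scan admits junk matches in non-coding frames; a
#' stop-bearing fragment is credible only alongside clean companion
#' evidence, and it is then kept in the model). Tail-to-tail neighbors
#' resolve on opposite strands.
#'
#' @param dna DNA string (a synteny interval or whole chromosome).
#' @param params A [grammar_params()].
#' @param cluster_gap Leftover fragments on one strand further apart than this
#'   many bp are not clustered together (default 1000).
#' @param pair_window Maximum exon-pair separation in bp (default 20000).
#' @param min_leftover_fingers Minimum finger count for a leftover cluster to
#'   be reported as a copy (default 2).
#' @return List of copies sorted by position, each a list with `model`,
#'   `status`, `g_start`, `g_end`, `strand`.
#' @export
scan_interval_copies <- function(dna, params = grammar_params(),
                                 cluster_gap = 1000L, pair_window = 20000L,
                                 min_leftover_fingers = 2L) {
  hits <- six_frame_scan(dna, params)
  if (!length(hits)) return(list())
  copies <- list()
  add_copy <- function(frags, strand) {
    model <- assemble_gene_model(frags, dna, pair_window)
    copies[[length(copies) + 1L]] <<- list(
      model = model, status = call_status(model),
      g_start = min(vapply(frags, `[[`, numeric(1), "g_start")),
      g_end = max(vapply(frags, `[[`, numeric(1), "g_end")),
      strand = strand)
  }
  for (strand in c("+", "-")) {
    sh <- hits[vapply(hits, `[[`, character(1), "strand") == strand]
    if (!length(sh)) next
    nf <- vapply(sh, `[[`, integer(1), "n_fingers")
    used <- logical(length(sh))

    ## stage 1: splice-consistent exon pairs
    pairs <- list()
    for (i in which(nf == 1L)) {
      for (j in which(nf == 2L)) {
        h1 <- sh[[i]]; h2 <- sh[[j]]
        upstream_first <- if (strand == "+") h1$g_end <= h2$g_start else h2$g_end <= h1$g_start
        if (!upstream_first) next
        gap_iv <- if (strand == "+") c(h1$g_end, h2$g_start) else c(h2$g_end, h1$g_start)
        gap_bp <- gap_iv[2] - gap_iv[1]
        if (gap_bp > pair_window) next
        gap_dna <- substring(dna, gap_iv[1] + 1L, gap_iv[2])
        if (strand == "-") gap_dna <- reverse_complement(gap_dna)
        if (is.null(find_consistent_splice(gap_dna))) next
        pairs[[length(pairs) + 1L]] <- c(i, j, gap_bp)
      }
    }
    if (length(pairs)) {
      pm <- do.call(rbind, pairs)
      pm <- pm[order(pm[, 3]), , drop = FALSE]
      for (r in seq_len(nrow(pm))) {
        i <- pm[r, 1]; j <- pm[r, 2]
        if (used[i] || used[j]) next
        used[c(i, j)] <- TRUE
        add_copy(list(sh[[i]], sh[[j]]), strand)
      }
    }

    ## stage 2: complete single-fragment copies
    for (i in which(nf >= 3L & !used)) {
      used[i] <- TRUE
      add_copy(list(sh[[i]]), strand)
    }

    ## stage 3: leftovers, clustered by proximity
    left <- which(!used)
    if (length(left)) {
      starts <- vapply(sh[left], `[[`, numeric(1), "g_start")
      ends <- vapply(sh[left], `[[`, numeric(1), "g_end")
      ord <- order(starts)
      left <- left[ord]; starts <- starts[ord]; ends <- ends[ord]
      grp <- cumsum(c(1, starts[-1] > cummax(ends)[-length(ends)] + cluster_gap))
      for (g in unique(grp)) {
        cl <- sh[left[grp == g]]
        clean_fingers <- sum(vapply(cl, function(h) {
          if (length(h$stop_aa)) 0L else h$n_fingers
        }, integer(1)))
        if (clean_fingers < min_leftover_fingers) next
        add_copy(cl, strand)
      }
    }
  }
  copies[order(vapply(copies, `[[`, numeric(1), "g_start"))]
}
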