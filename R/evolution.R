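#' Anchor-based alignment of zinc-finger regions
#'
#' Aligns three-finger regions by mapping each sequence's twelve zinc-binding
#' C/H anchors onto shared anchor columns. Inter-anchor spans of unequal
#' length are padded with gaps right-aligned against the downstream anchor, so
#' deletions (e.g. the two-residue contractions between the first cysteines of
#' rat KLF18 fingers) appear immediately after the upstream anchor. The result
#' is deterministic and degapping any row recovers its input region exactly.
#'
#' @param regions List of per-protein lists with `id`, `fingers` (three-row
#'   data.frame from [find_c2h2_domains()], coordinates into `sequence`), and
#'   `sequence` (the protein or region the coordinates index).
#' @return An `anchored_alignment` list: `ids`, `aligned` (named character
#'   vector of equal-length gapped strings), `anchor_cols` (1-based columns
#'   holding the C/H anchors).
#' @export
anchor_align <- function(regions) {
  stopifnot(length(regions) >= 1L)
  for (r in regions) {
    if (nrow(r$fingers) != 3L) {
      stop("finger-count mismatch: region '", r$id, "' has ", nrow(r$fingers),
           " fingers, need 3")
    }
  }
  ## per row: the 12 anchor positions (0-based) and the 11 inter-anchor spans
  pieces <- lapply(regions, function(r) {
    anchors <- as.integer(t(as.matrix(r$fingers[, c("c1", "c2", "h1", "h2")])))
    spans <- character(11L)
    for (k in 1:11) {
      spans[k] <- substring(r$sequence, anchors[k] + 2L, anchors[k + 1L])
    }
    list(id = r$id,
         anchor_res = vapply(anchors + 1L, function(p) substring(r$sequence, p, p),
                             character(1)),
         spans = spans)
  })
  widths <- sapply(1:11, function(k) {
    max(vapply(pieces, function(p) nchar(p$spans[k]), integer(1)))
  })
  aligned <- vapply(pieces, function(p) {
    s <- p$anchor_res[1]
    for (k in 1:11) {
      pad <- strrep("-", widths[k] - nchar(p$spans[k]))
      s <- paste0(s, pad, p$spans[k], p$anchor_res[k + 1L])
    }
    s
  }, character(1))
  names(aligned) <- vapply(pieces, `[[`, character(1), "id")
  anchor_cols <- cumsum(c(1L, widths + 1L))
  structure(list(ids = names(aligned), aligned = aligned,
                 anchor_cols = anchor_cols),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("<anchored_alignment> %d rows x %d columns (%d anchor columns)\n",
              length(x$aligned), nchar(x$aligned[1]), length(x$anchor_cols)))
  invisible(x)
}

as_alignment_matrix <- function(alignment) {
  aligned <- if (inherits(alignment, "anchored_alignment")) alignment$aligned else alignment
  stopifnot(is.character(aligned), length(unique(nchar(aligned))) == 1L)
  m <- do.call(rbind, strsplit(aligned, ""))
  rownames(m) <- names(aligned)
  m
}

#' Pairwise distances from an alignment
#'
#' Mismatch fraction (p-distance) over columns where both rows are ungapped,
#' optionally Poisson-corrected (`-ln(1 - p)`), for input to tree building.
#'
#' @param alignment An `anchored_alignment` or named character vector of
#'   equal-length aligned strings (at least two rows).
#' @param correction `"none"` (default) or `"poisson"`; the Poisson correction
#'   is undefined as p approaches 1 and errors when `p >= 0.75`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(shared)) {
        stop("no shared ungapped columns between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      }
      p <- mean(m[i, shared] != m[j, shared])
      if (correction == "poisson") {
        if (p >= 0.75) stop("Poisson correction undefined for p >= 0.75 (p = ", p, ")")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining of a distance matrix (via
#' \code{\link[ape]{nj}}); negative branch lengths are clamped to zero. NJ is
#' used here as a deterministic distance-based stand-in for likelihood tree
#' building: the quantities carried downstream are topological (clade
#' membership), not branch support.
#'
#' @param d Symmetric distance matrix with at least 3 taxa.
#' @return An \code{ape::phylo} tree (unrooted).
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Monophyly test under outgroup rooting
#'
#' Roots the tree at the given outgroup leaf and asks whether the taxa form a
#' complete clade. A singleton set is monophyletic by convention.
#'
#' @param tree An \code{ape::phylo} tree.
#' @param outgroup_id Leaf label to root at.
#' @param taxa Character vector of leaf labels (must not contain the outgroup).
#' @return Logical.
#' @export
is_monophyletic <- function(tree, outgroup_id, taxa) {
  stopifnot(outgroup_id %in% tree$tip.label, all(taxa %in% tree$tip.label))
  if (outgroup_id %in% taxa) stop("taxa set must not contain the outgroup")
  if (length(taxa) <= 1L) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Infer a duplication / retrotransposition event history
#'
#' Reconstructs the parent of each family member as its nearest homolog by
#' sequence identity (global pairwise alignment), growing outward from a
#' designated root so the parent graph is acyclic by construction, and labels
#' each parent-child edge with a mechanism:
#' \itemize{
#'   \item \code{RT} (retrotransposition) — the child is intronless and either
#'     its parent is intron-containing (a retrocopy of a spliced mRNA) or the
#'     copy is distal (serial retrotransposition of an already-intronless
#'     parent); the retrocopy hallmark is the intronless coding region.
#'   \item \code{LGD} (local gene duplication) — the child lies on the parent's
#'     chromosome within \code{locality_bp}.
#'   \item \code{distal_unknown} — a distal intron-containing copy.
#' }
#' Identity ties are broken by id order (a warning is logged), which matters
#' only at zero divergence.
#'
#' @param members data.frame with columns `id`, `chrom`, `start`,
#'   `intron_structure` (`intron_containing` / `intronless`), `sequence`.
#' @param locality_bp Locality threshold for LGD calls (default 250000).
#' @param root_id Designated root member (default: first row).
#' @return An `event_history` list: `root`, `events` (data.frame `child`,
#'   `parent`, `mechanism`, `identity`, in parent-first order).
#' @export
classify_events <- function(members, locality_bp = 250000, root_id = NULL) {
  stopifnot(is.data.frame(members), nrow(members) >= 2L,
            all(c("id", "chrom", "start", "intron_structure", "sequence") %in% names(members)))
  if (anyDuplicated(members$id)) stop("duplicate member ids")
  if (is.null(root_id)) root_id <- members$id[1]
  stopifnot(root_id %in% members$id)
  n <- nrow(members)
  ids <- members$id
  aa <- Biostrings::AAStringSet(gsub("[^A-Z]", "X", toupper(members$sequence)))
  names(aa) <- ids
  pid <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pa <- Biostrings::pairwiseAlignment(aa[[i]], aa[[j]],
                                          substitutionMatrix = "BLOSUM62",
                                          gapOpening = 10, gapExtension = 0.5)
      pid[i, j] <- pid[j, i] <- Biostrings::pid(pa)
    }
  }
  placed <- root_id
  remaining <- setdiff(ids, root_id)
  events <- list()
  tie_seen <- FALSE
  while (length(remaining)) {
    cand <- expand.grid(child = remaining, parent = placed,
                        stringsAsFactors = FALSE)
    cand$identity <- pid[cbind(cand$child, cand$parent)]
    cand <- cand[order(-cand$identity, cand$child, cand$parent), , drop = FALSE]
    if (nrow(cand) > 1L && sum(cand$identity == cand$identity[1]) > 1L) tie_seen <- TRUE
    pick <- cand[1, ]
    child <- members[members$id == pick$child, ]
    parent <- members[members$id == pick$parent, ]
    mech <- if (child$intron_structure == "intronless" &&
                parent$intron_structure == "intron_containing") {
      "RT"
    } else if (child$chrom == parent$chrom &&
               abs(child$start - parent$start) <= locality_bp) {
      "LGD"
    } else if (child$intron_structure == "intronless") {
      "RT"
    } else "distal_unknown"
    events[[length(events) + 1L]] <- data.frame(
      child = pick$child, parent = pick$parent, mechanism = mech,
      identity = pick$identity, stringsAsFactors = FALSE)
    placed <- c(placed, pick$child)
    remaining <- setdiff(remaining, pick$child)
  }
  if (tie_seen) warning("identity ties broken by id order")
  structure(list(root = root_id, events = do.call(rbind, events)),
            class = "event_history")
}

#' @export
print.event_history <- function(x, ...) {
  cat(sprintf("<event_history> root %s, %d event(s)\n", x$root, nrow(x$events)))
  print(x$events)
  invisible(x)
}
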