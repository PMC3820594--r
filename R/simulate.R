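random_filler <- function(n) paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")

#' Random DNA
#'
#' I.i.d. uniform A/C/G/T filler used for intergenic sequence and flanks.
#' Draws from the current RNG stream; callers seed it.
#'
#' @param n Length in bp.
#' @return DNA string.
#' @export
random_dna <- function(n) paste(sample(DNA_STANDARD, n, replace = TRUE), collapse = "")

## One 14-residue repeat unit: two filler residues, the Q-T-L context most
## often seen before the conserved tyrosine, the 4-residue motif, then five
## filler residues. Exactly one motif match per unit, spaced 14 apart when
## units are concatenated.
repeat_unit <- function(y_prob = 0.9) {
  first <- sample(c("Y", "C"), 1L, prob = c(y_prob, 1 - y_prob))
  small <- sample(c("G", "A", "S", "T", "D", "N", "P", "E"), 1L)
  last <- sample(c("Q", "H"), 1L, prob = c(0.8, 0.2))
  paste0(random_filler(2L), "QTL", first, sample(FILLER_AA, 1L), small, last,
         random_filler(5L))
}

#' Generate a zinc-finger protein with planted structure
#'
#' Constructs a protein from the family grammars: an N-terminal region of
#' `n_repeats` tandem 14-residue repeat units (each containing one
#' `[YC]x[GASTDNPE][QH]` motif with KLF18-like residue preferences), then a
#' zinc-finger region with the requested cysteine-pair separations, canonical
#' inner/histidine gaps and 7-residue linkers, with the conserved DNA-contact
#' arginines and acidic partners planted at the [contact_spec()] offsets.
#' Filler residues exclude C, H and Y, so the planted fingers and motifs are
#' exactly the ones any detector can find. Deterministic per seed.
#'
#' @param id Protein id.
#' @param cys_gaps Integer vector of cysteine-pair separations, one per finger
#'   (default the SP/KLF consensus `c(4, 4, 2)`; use `c(4, 2, 2)` for an
#'   EGR-like decoy, `c(4, 4, 2, 4)` for a WT1-like one).
#' @param n_repeats Number of N-terminal repeat units (default 14).
#' @param seed RNG seed (mandatory).
#' @param terminal_his Residue at the last zinc-binding position of the final
#'   finger, `"H"` (default) or `"C"` (the mouse-candidate variant).
#' @param y_prob Probability that a repeat unit starts with Y rather than C
#'   (default 0.9; set 0 for a keratin-like decoy).
#' @param spec A [contact_spec()] giving where to plant contact residues.
#' @param linker_length Inter-finger linker length (default 7).
#' @return A [protein_record()].
#' @export
make_zf_protein <- function(id, cys_gaps = c(4L, 4L, 2L), n_repeats = 14L,
                            seed, terminal_his = c("H", "C"), y_prob = 0.9,
                            spec = contact_spec(), linker_length = 7L) {
  terminal_his <- match.arg(terminal_his)
  stopifnot(all(cys_gaps >= 0L), n_repeats >= 0L)
  with_seed(seed, {
    nf <- length(cys_gaps)
    fingers <- character(nf)
    for (k in seq_len(nf)) {
      spacer <- sample(FILLER_AA, 12L, replace = TRUE)
      plant <- spec[spec$finger == k, , drop = FALSE]
      for (r in seq_len(nrow(plant))) {
        spacer[plant$offset[r] + 1L] <-
          if (plant$class[r] == "R") "R" else if (plant$offset[r] == 8L) "E" else "D"
      }
      last <- if (k == nf) terminal_his else "H"
      fingers[k] <- paste0("C", random_filler(cys_gaps[k]), "C",
                           paste(spacer, collapse = ""), "H", random_filler(3L), last)
    }
    zf <- fingers[1]
    if (nf > 1L) {
      for (k in 2:nf) zf <- paste0(zf, random_filler(linker_length), fingers[k])
    }
    repeats <- paste(vapply(seq_len(n_repeats), function(i) repeat_unit(y_prob),
                            character(1)), collapse = "")
    seq <- paste0("M", random_filler(9L), repeats, random_filler(20L),
                  zf, random_filler(10L))
    ## chance motif matches can only open at an anchor cysteine (filler has no
    ## Y/C); neutralize them so the planted repeat count is exact. The residue
    ## three after an anchor C is always free filler/spacer (contacts sit at
    ## offsets 5/7/8/11), so rewriting it to L is safe.
    planted <- 10L + 14L * (seq_len(n_repeats) - 1L) + 5L       # 0-based starts
    extra <- setdiff(scan_motif(seq)$start, planted)
    if (length(extra)) {
      chars <- seq_chars(seq)
      chars[extra + 4L] <- "L"
      seq <- paste(chars, collapse = "")
    }
    protein_record(id, seq, source_tag = "synthetic")
  })
}

codons_for_residue <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Build a genomic locus for a protein
#'
#' Back-translates a three-finger protein with uniform seeded codon choice and
#' plants the requested gene structure: optionally an intron between the
#' coding regions of the first zinc finger and the last two (canonical GT..AG
#' boundaries, or CT..AC as a non-canonical negative control guaranteed free
#' of coincidental splice-consistent GT..AG pairs), optionally a premature
#' TAA stop codon inside a chosen finger's spacer or a destroyed zinc-binding
#' anchor, optionally hard-masking of the whole finger-coding region with N
#' (emulating an assembly gap). Random flanks surround the coding sequence.
#'
#' @param protein A three-finger [protein_record()] (e.g. from
#'   [make_zf_protein()]).
#' @param intron_plan `"none"`, `"GT_AG_between_f1_f2"`, or
#'   `"CT_AC_between_f1_f2"`.
#' @param pseudogenize `NULL` for a clean locus; an integer 1-3 to plant a TAA
#'   stop inside that finger's spacer; or `"anchor"` to mutate the second
#'   finger's first cysteine codon to arginine (a deteriorated finger).
#' @param seed RNG seed.
#' @param flank_bp Random flank length on each side (default 300).
#' @param intron_length Total intron length including boundaries (default 101;
#'   deliberately not a multiple of 3 so the downstream exon shifts frame).
#' @param mask_fingers Replace the finger-coding DNA (intron included) with N.
#' @return List with `dna`, `feature` (0-based half-open gene interval on
#'   `+`), and `truth` (planted status, intron structure, stop position).
#' @export
make_locus <- function(protein, intron_plan = c("none", "GT_AG_between_f1_f2",
                                                "CT_AC_between_f1_f2"),
                       pseudogenize = NULL, seed, flank_bp = 300L,
                       intron_length = 101L, mask_fingers = FALSE) {
  intron_plan <- match.arg(intron_plan)
  fingers <- find_c2h2_domains(protein)
  if (nrow(fingers) != 3L) stop("locus construction needs a three-finger protein")
  seq <- as_sequence(protein)
  nres <- nchar(seq)
  with_seed(seed, {
    tab <- codons_for_residue()
    chars <- seq_chars(seq)
    codons <- vapply(chars, function(a) {
      opts <- tab[[a]]
      if (is.null(opts)) opts <- tab[["X"]] %||% "NNN"
      if (a == "X") return("NNN")
      opts[sample.int(length(opts), 1L)]
    }, character(1))

    stop_res <- NA_integer_
    if (!is.null(pseudogenize)) {
      if (identical(pseudogenize, "anchor")) {
        codons[fingers$c1[2] + 1L] <- "CGT"            # C -> R, finger 2 anchor lost
      } else {
        k <- as.integer(pseudogenize)
        stopifnot(k >= 1L, k <= 3L)
        stop_res <- fingers$c2[k] + 2L                  # spacer position, 0-based
        codons[stop_res + 1L] <- "TAA"
      }
    }

    cut_res <- fingers$h2[1] + 4L                       # mid-linker residue, 0-based
    exon1 <- paste(codons[seq_len(cut_res + 1L)], collapse = "")
    exon2 <- paste(codons[(cut_res + 2L):nres], collapse = "")
    intron <- NULL
    if (intron_plan != "none") {
      bounds <- if (intron_plan == "GT_AG_between_f1_f2") c("GT", "AG") else c("CT", "AC")
      ## the inter-fragment gap the assembler will inspect: linker codons of
      ## exon1 after finger 1, the intron, linker codons of exon2 before
      ## finger 2
      gap_left <- paste(codons[(fingers$h2[1] + 2L):(cut_res + 1L)], collapse = "")
      gap_right <- paste(codons[(cut_res + 2L):fingers$c1[2]], collapse = "")
      for (try in 1:200) {
        intron <- paste0(bounds[1], random_dna(intron_length - 4L), bounds[2])
        gap <- paste0(gap_left, intron, gap_right)
        sp <- find_consistent_splice(gap)
        ok <- if (intron_plan == "GT_AG_between_f1_f2") !is.null(sp) else is.null(sp)
        if (ok) break
        intron <- NULL
      }
      if (is.null(intron)) stop("could not realize the requested intron plan")
    }
    cds <- if (is.null(intron)) paste0(exon1, exon2)
           else paste0(exon1, intron, exon2)
    gene <- paste0(cds, "TAA")
    dna <- paste0(random_dna(flank_bp), gene, random_dna(flank_bp))

    finger_dna <- c(3L * fingers$c1[1],
                    3L * (fingers$h2[3] + 1L) + if (is.null(intron)) 0L else nchar(intron))
    if (mask_fingers) {
      dna <- paste0(substring(dna, 1L, flank_bp + finger_dna[1]),
                    strrep("N", finger_dna[2] - finger_dna[1]),
                    substring(dna, flank_bp + finger_dna[2] + 1L))
    }
    stop_genomic <- if (is.na(stop_res)) NA_real_ else {
      flank_bp + 3L * stop_res + if (!is.null(intron) && stop_res > cut_res) nchar(intron) else 0L
    }
    status <- if (mask_fingers) "masked"
      else if (!is.null(pseudogenize)) "pseudogene"
      else "coding"
    list(dna = dna,
         feature = data.frame(gene_id = protein$id, chrom = NA_character_,
                              start = flank_bp, end = flank_bp + nchar(gene),
                              strand = "+", stringsAsFactors = FALSE),
         truth = list(status = status,
                      intron_structure = switch(intron_plan,
                                                none = "intronless",
                                                GT_AG_between_f1_f2 = "intron_containing",
                                                CT_AC_between_f1_f2 = "noncanonical"),
                      stop_genomic = stop_genomic,
                      finger_dna = flank_bp + finger_dna,
                      n_repeats = NA_integer_))
  })
}

#' Assemble a synthetic genome with planted KLF-like loci
#'
#' Lays out one chromosome with the upstream anchor genes, the planted
#' KLF-like copies (tandem, in plan order, with requested strands so
#' tail-to-tail arrangements can be planted), and the downstream anchor genes,
#' all separated by random intergenic filler; distal copies go to a second
#' chromosome. Emits the genome sequence, its gene table, and a truth table
#' with exact coordinates.
#'
#' @param genome_id Genome label.
#' @param copy_plan data.frame with one row per planted copy: `gene_id`,
#'   `placement` (`"tandem"`/`"distal"`), `strand`, `intron` (an
#'   [make_locus()] intron plan), `pseudogenize` (`NA`, finger index, or
#'   `"anchor"`), `n_repeats`, `mask` (logical). Zero rows plant anchors only.
#' @param seed RNG seed.
#' @param anchors Anchor layout, default [klf_anchor_genes()].
#' @return List `genome_id`, `seqs` (named chromosome DNA), `table`
#'   ([gene_table()]), `truth` (data.frame, one row per planted copy).
#' @export
make_genome <- function(genome_id, copy_plan = empty_copy_plan(), seed,
                        anchors = klf_anchor_genes()) {
  stopifnot(is.data.frame(copy_plan))
  with_seed(seed, {
    feats <- list(); truth <- list()
    build_chrom <- function(chrom, plan, with_anchors) {
      parts <- character(0); cursor <- 0L
      emit <- function(dna) { parts[[length(parts) + 1L]] <<- dna; cursor <<- cursor + nchar(dna) }
      add_gene <- function(gene_id, start, end, strand) {
        feats[[length(feats) + 1L]] <<- data.frame(
          gene_id = gene_id, chrom = chrom, start = start, end = end,
          strand = strand, stringsAsFactors = FALSE)
      }
      emit(random_dna(1200L))
      if (with_anchors) {
        for (a in anchors$upstream) {
          add_gene(a, cursor, cursor + 600L, "+")
          emit(random_dna(600L)); emit(random_dna(400L))
        }
      }
      if (nrow(plan)) {
        for (r in seq_len(nrow(plan))) {
          row <- plan[r, ]
          prot <- make_zf_protein(row$gene_id, n_repeats = row$n_repeats,
                                  seed = substream_seed(seed, paste0(chrom, row$gene_id)))
          ps <- row$pseudogenize
          ps <- if (is.na(ps)) NULL else if (ps == "anchor") "anchor" else as.integer(ps)
          loc <- make_locus(prot, intron_plan = row$intron, pseudogenize = ps,
                            seed = substream_seed(seed, paste0("locus", row$gene_id)),
                            flank_bp = 200L, mask_fingers = isTRUE(row$mask))
          dna <- loc$dna; fstart <- loc$feature$start; fend <- loc$feature$end
          if (row$strand == "-") {
            dna <- reverse_complement(dna)
            w <- nchar(dna)
            tmp <- w - fend; fend <- w - fstart; fstart <- tmp
          }
          add_gene(row$gene_id, cursor + fstart, cursor + fend, row$strand)
          truth[[length(truth) + 1L]] <<- data.frame(
            genome_id = genome_id, gene_id = row$gene_id, chrom = chrom,
            start = cursor + fstart, end = cursor + fend, strand = row$strand,
            status = loc$truth$status, intron_structure = loc$truth$intron_structure,
            stop_genomic = if (row$strand == "+" && !is.na(loc$truth$stop_genomic))
              cursor + loc$truth$stop_genomic else NA_real_,
            n_repeats = row$n_repeats, stringsAsFactors = FALSE)
          emit(dna); emit(random_dna(300L))
        }
      }
      if (with_anchors) {
        emit(random_dna(400L))
        for (a in anchors$downstream) {
          add_gene(a, cursor, cursor + 600L, "+")
          emit(random_dna(600L)); emit(random_dna(400L))
        }
      }
      emit(random_dna(800L))
      paste(parts, collapse = "")
    }
    tandem <- copy_plan[copy_plan$placement == "tandem", , drop = FALSE]
    distal <- copy_plan[copy_plan$placement == "distal", , drop = FALSE]
    seqs <- c(chr1 = build_chrom("chr1", tandem, with_anchors = TRUE))
    if (nrow(distal)) seqs <- c(seqs, chr2 = build_chrom("chr2", distal, FALSE))
    features <- do.call(rbind, feats)
    truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
    list(genome_id = genome_id, seqs = seqs,
         table = gene_table(genome_id, features),
         truth = truth_df)
  })
}

#' @rdname make_genome
#' @export
empty_copy_plan <- function() {
  data.frame(gene_id = character(0), placement = character(0), strand = character(0),
              intron = character(0), pseudogenize = character(0),
              n_repeats = integer(0), mask = logical(0), stringsAsFactors = FALSE)
}

copy_plan_row <- function(gene_id, placement = "tandem", strand = "+",
                          intron = "GT_AG_between_f1_f2", pseudogenize = NA,
                          n_repeats = 14L, mask = FALSE) {
  data.frame(gene_id = gene_id, placement = placement, strand = strand,
             intron = intron, pseudogenize = as.character(pseudogenize),
             n_repeats = n_repeats, mask = mask, stringsAsFactors = FALSE)
}

#' Simulate a multi-genome survey panel
#'
#' Generates `n_genomes` synthetic genomes whose anchored loci realize a
#' planned mix of genome-level statuses, emulating a mammalian genome survey:
#' coding loci (one to three tandem copies), stop-codon pseudogenes, genomes
#' with anchors but no locus, and genomes whose finger-coding DNA is masked
#' but whose repeat region survives (`partial`). Repeat counts are drawn
#' uniformly from `repeat_range`.
#'
#' @param n_genomes Number of genomes (default 20).
#' @param seed RNG seed.
#' @param statuses Optional character vector (length `n_genomes`) of planted
#'   genome statuses from `coding`/`pseudogene`/`absent`/`partial`; the
#'   default mix is proportioned like a placental-mammal survey (majority
#'   coding, a few pseudogenes, a few missing).
#' @param repeat_range Inclusive range for per-gene repeat counts
#'   (default `c(10, 50)`).
#' @return List with `genomes` (list of [make_genome()] results) and `truth`
#'   (data.frame `genome_id`, `status`, `n_copies`).
#' @export
simulate_panel <- function(n_genomes = 20L, seed,
                           statuses = NULL, repeat_range = c(10L, 50L)) {
  if (is.null(statuses)) {
    base <- c(rep("coding", ceiling(0.7 * n_genomes)),
              rep("pseudogene", max(1L, round(0.1 * n_genomes))),
              rep("absent", max(1L, round(0.1 * n_genomes))),
              rep("partial", max(1L, round(0.1 * n_genomes))))
    statuses <- base[seq_len(n_genomes)]
  }
  stopifnot(length(statuses) == n_genomes,
            all(statuses %in% c("coding", "pseudogene", "absent", "partial")))
  genomes <- vector("list", n_genomes)
  truth <- vector("list", n_genomes)
  for (i in seq_len(n_genomes)) {
    gid <- sprintf("genome%02d", i)
    gseed <- substream_seed(seed, gid)
    nrep <- with_seed(gseed, sample(repeat_range[1]:repeat_range[2], 3L, replace = TRUE))
    plan <- switch(statuses[i],
      coding = {
        k <- 1L + (i %% 3L)
        do.call(rbind, lapply(seq_len(k), function(j) {
          copy_plan_row(sprintf("KLF18_%s_c%d", gid, j), n_repeats = nrep[j])
        }))
      },
      pseudogene = copy_plan_row(sprintf("KLF18_%s_psi", gid), pseudogenize = 2L,
                                 n_repeats = nrep[1]),
      absent = empty_copy_plan(),
      partial = copy_plan_row(sprintf("KLF18_%s_part", gid), mask = TRUE,
                              n_repeats = nrep[1]))
    genomes[[i]] <- make_genome(gid, plan, seed = gseed)
    truth[[i]] <- data.frame(genome_id = gid, status = statuses[i],
                             n_copies = if (statuses[i] == "coding") nrow(plan)
                                        else if (statuses[i] == "pseudogene") 1L else 0L,
                             stringsAsFactors = FALSE)
  }
  list(genomes = genomes, truth = do.call(rbind, truth))
}

#' Point-substitution mutation of a sequence
#'
#' Per-site substitution with probability `rate`; a mutated site is replaced
#' by a uniform draw from the other letters of the alphabet. Positions listed
#' in `protect` (1-based) are never touched — used to keep zinc-binding
#' anchors intact when simulating divergence of finger regions. Deterministic
#' per seed.
#'
#' @param seq Character sequence (protein by default).
#' @param rate Substitution probability per site, in `[0, 1)`.
#' @param seed RNG seed.
#' @param alphabet Replacement alphabet (default the 20 amino acids; pass
#'   `c("A","C","G","T")` for DNA).
#' @param protect Integer vector of 1-based positions to leave untouched.
#' @return Mutated sequence string.
#' @export
mutate_residues <- function(seq, rate, seed, alphabet = AA_STANDARD,
                            protect = integer(0)) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(seq)
  with_seed(seed, {
    chars <- seq_chars(seq)
    hit <- which(stats::runif(length(chars)) < rate)
    hit <- setdiff(hit, protect)
    for (i in hit) {
      chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Members of the murine KLF expansion scenario
#'
#' Builds the five-member family behind the murine expansion model: a
#' KLF17-like root, its tail-to-tail chromosomal neighbor KLF18 (local gene
#' duplication; both intron-containing), a distal intronless retrocopy
#' (Zfp352-like, retrotransposition of the spliced KLF18 mRNA), its adjacent
#' intronless tandem copy (Zfp352l-like, local duplication), and a further
#' distal intronless retrocopy (Zfp353-like). Sequences diverge serially
#' along the true parent chain at `rate` per branch with the zinc-binding
#' anchors protected, so nearest-identity parent recovery is well posed at
#' nonzero divergence.
#'
#' @param seed RNG seed.
#' @param rate Per-branch substitution rate (default 0.05).
#' @param n_repeats Repeat count of the root protein (default 30).
#' @return List with `members` (data.frame for [classify_events()]) and
#'   `truth` (data.frame `child`, `parent`, `mechanism` in event order).
#' @export
murine_members <- function(seed, rate = 0.05, n_repeats = 30L) {
  root <- make_zf_protein("KLF17", n_repeats = n_repeats,
                          seed = substream_seed(seed, "murine_root"))
  fingers <- find_c2h2_domains(root)
  protect <- sort(c(fingers$c1, fingers$c2, fingers$h1, fingers$h2)) + 1L
  evolve <- function(parent_seq, tag) {
    mutate_residues(parent_seq, rate, seed = substream_seed(seed, tag),
                    protect = protect)
  }
  s_klf17 <- root$sequence
  s_klf18 <- evolve(s_klf17, "klf18")
  s_zfp352 <- evolve(s_klf18, "zfp352")
  s_zfp352l <- evolve(s_zfp352, "zfp352l")
  s_zfp353 <- evolve(s_zfp352, "zfp353")
  members <- data.frame(
    id = c("KLF17", "KLF18", "Zfp352", "Zfp352l", "Zfp353"),
    chrom = c("chr4", "chr4", "chr13", "chr13", "chr5"),
    start = c(1000000, 1030000, 5000000, 5030000, 2000000),
    intron_structure = c("intron_containing", "intron_containing",
                         "intronless", "intronless", "intronless"),
    sequence = c(s_klf17, s_klf18, s_zfp352, s_zfp352l, s_zfp353),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    child = c("KLF18", "Zfp352", "Zfp352l", "Zfp353"),
    parent = c("KLF17", "KLF18", "Zfp352", "Zfp352"),
    mechanism = c("LGD", "RT", "LGD", "RT"),
    stringsAsFactors = FALSE)
  list(members = members, truth = truth)
}

#' Simulate a KLF family with a fast-evolving planted clade
#'
#' Emulates the phylogenetic setting of the family: background members diverge
#' independently from a common ancestral three-finger region at `base_rate`,
#' while a KLF17/KLF18-like pair shares an extra fast branch (`shared_rate`,
#' i.e. an elevated evolutionary rate) before splitting; a WT1-like row
#' diverged furthest serves as outgroup. Zinc-binding anchors are protected so
#' every row keeps its parseable three-finger structure.
#'
#' @param seed RNG seed.
#' @param n_background Number of background KLF-like rows (default 10).
#' @param base_rate Per-branch substitution rate of background rows and of the
#'   pair's terminal branches (default 0.08).
#' @param shared_rate Rate on the pair's shared branch (default 0.15).
#' @param outgroup_rate Rate on the outgroup branch (default 0.3).
#' @return List with `regions` (input for [anchor_align()]), `clade`
#'   (the KLF17/KLF18-like ids), `outgroup` (id).
#' @export
simulate_klf_family <- function(seed, n_background = 10L, base_rate = 0.08,
                                shared_rate = 0.15, outgroup_rate = 0.3) {
  anc <- make_zf_protein("ancestor", seed = substream_seed(seed, "family_anc"),
                         n_repeats = 0L)
  fingers <- find_c2h2_domains(anc)
  region <- extract_zf_region(anc, fingers)
  rel <- fingers
  for (col in c("c1", "c2", "h1", "h2")) rel[[col]] <- rel[[col]] - fingers$c1[1]
  protect <- sort(c(rel$c1, rel$c2, rel$h1, rel$h2)) + 1L
  ev <- function(s, rate, tag) {
    mutate_residues(s, rate, seed = substream_seed(seed, tag), protect = protect)
  }
  regions <- list()
  add <- function(id, s) {
    regions[[length(regions) + 1L]] <<- list(id = id, fingers = rel, sequence = s)
  }
  for (i in seq_len(n_background)) {
    add(sprintf("KLF%02d", i), ev(region, base_rate, paste0("bg", i)))
  }
  pair_anc <- ev(region, shared_rate, "pair_anc")
  add("KLF17", ev(pair_anc, base_rate, "klf17"))
  add("KLF18", ev(pair_anc, base_rate, "klf18"))
  add("WT1", ev(region, outgroup_rate, "wt1"))
  list(regions = regions, clade = c("KLF17", "KLF18"), outgroup = "WT1")
}
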