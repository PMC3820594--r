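region_of <- function(p) {
  f <- find_c2h2_domains(p)
  list(id = p$id, fingers = f, sequence = p$sequence)
}

test_that("anchor alignment is gap-free for identical regions and localizes deletions", {
  cons <- make_zf_protein("consensus", seed = 1, n_repeats = 0L)
  twin <- protein_record("twin", cons$sequence)
  aln <- anchor_align(list(region_of(cons), region_of(twin)))
  expect_false(any(grepl("-", aln$aligned)))
  expect_equal(unname(aln$aligned[1]), unname(aln$aligned[2]))

  # rat-like contraction of finger-1 cysteine spacing: a 2-column gap inside
  # finger 1 of the rat-like row, between its cysteines
  rat <- make_zf_protein("rat", cys_gaps = c(2, 4, 2), seed = 2, n_repeats = 0L)
  aln2 <- anchor_align(list(region_of(cons), region_of(rat)))
  rat_row <- aln2$aligned[["rat"]]
  gap_cols <- which(strsplit(rat_row, "")[[1]] == "-")
  expect_length(gap_cols, 2L)
  expect_true(all(gap_cols > aln2$anchor_cols[1] & gap_cols < aln2$anchor_cols[2]))
  expect_false(grepl("-", aln2$aligned[["consensus"]]))
})

test_that("degapping aligned rows recovers every input region", {
  for (s in 1:10) {
    gaps <- list(c(4, 4, 2), c(2, 4, 2), c(2, 2, 2), c(4, 2, 2))[[1 + (s %% 4)]]
    prots <- list(make_zf_protein("a", seed = s, n_repeats = 0L),
                  make_zf_protein("b", cys_gaps = gaps, seed = s + 100, n_repeats = 0L))
    regions <- lapply(prots, region_of)
    aln <- anchor_align(regions)
    for (r in regions) {
      expect_equal(gsub("-", "", aln$aligned[[r$id]]),
                   extract_zf_region(r$sequence, r$fingers))
    }
    # anchor columns carry only C/H
    m <- do.call(rbind, strsplit(aln$aligned, ""))
    expect_true(all(m[, aln$anchor_cols] %in% c("C", "H")))
  }
})

test_that("p-distances count mismatches over shared ungapped columns", {
  rows <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL")
  expect_equal(p_distance(rows)["a", "b"], 0)
  rows2 <- c(a = paste(rep("A", 50), collapse = ""),
             b = paste(c(rep("C", 5), rep("A", 45)), collapse = ""))
  expect_equal(p_distance(rows2)["a", "b"], 0.1)
  # brute-force recount on a random gapped pair
  withr::with_seed(77, {
    a <- strsplit(random_aa_seq(80), "")[[1]]
    b <- strsplit(random_aa_seq(80), "")[[1]]
    a[sample(80, 10)] <- "-"; b[sample(80, 10)] <- "-"
    shared <- a != "-" & b != "-"
    want <- mean(a[shared] != b[shared])
    rows3 <- c(x = paste(a, collapse = ""), y = paste(b, collapse = ""))
    expect_equal(p_distance(rows3)["x", "y"], want)
    d <- p_distance(rows3)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
  })
  expect_error(p_distance(c(a = "A---", b = "-CC-")), "shared")
  expect_error(p_distance(c(a = strrep("A", 100), b = strrep("C", 100)),
                          correction = "poisson"), "0.75")
  rows4 <- c(a = strrep("A", 10), b = paste0("C", strrep("A", 9)))
  expect_equal(p_distance(rows4, correction = "poisson")["a", "b"], -log(1 - 0.1))
})

test_that("three-taxon neighbor joining solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (2 + 3 - 3) / 2)
  expect_equal(unname(bl["b"]), (2 + 3 - 3) / 2)
  expect_equal(unname(bl["c"]), (3 + 3 - 2) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining recovers additive topologies, validated by exhaustive least squares", {
  skip_if_not_installed("phangorn")
  withr::with_seed(42, {
    for (n in c(5, 6)) {
      for (rep in 1:5) {
        true_tree <- ape::rtree(n, rooted = FALSE,
                                tip.label = paste0("t", seq_len(n)))
        true_tree$edge.length <- true_tree$edge.length + 0.1
        d <- ape::cophenetic.phylo(true_tree)
        d <- d[paste0("t", 1:n), paste0("t", 1:n)]
        got <- nj_tree(d)
        expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(got)), 0,
                     ignore_attr = TRUE)
        # independent oracle: best least-squares fit over every topology
        all_topo <- phangorn::allTrees(n, rooted = FALSE, tip.label = rownames(d))
        rss <- vapply(all_topo, function(tp) {
          fit <- phangorn::nnls.tree(d, tp, method = "unrooted")
          sum((ape::cophenetic.phylo(fit)[rownames(d), colnames(d)] - d)^2)
        }, numeric(1))
        best <- all_topo[[which.min(rss)]]
        expect_equal(ape::dist.topo(ape::unroot(best), ape::unroot(got)), 0,
                     ignore_attr = TRUE)
        # permutation invariance of the input order
        perm <- sample(n)
        got2 <- nj_tree(d[perm, perm])
        expect_equal(ape::dist.topo(ape::unroot(got), ape::unroot(got2)), 0,
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("monophyly testing under outgroup rooting behaves on enumerable trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,OUT:1):1);")
  expect_true(is_monophyletic(tr, "OUT", c("A", "B")))
  expect_false(is_monophyletic(tr, "OUT", c("A", "C")))
  expect_true(is_monophyletic(tr, "OUT", "A"))
  expect_error(is_monophyletic(tr, "OUT", c("A", "OUT")), "outgroup")
})

test_that("event classification recovers the planted murine history and stays acyclic", {
  sc <- murine_members(seed = 7, rate = 0.05)
  eh <- suppressWarnings(classify_events(sc$members, root_id = "KLF17"))
  ev <- eh$events[match(sc$truth$child, eh$events$child), ]
  expect_equal(ev$mechanism, sc$truth$mechanism)
  expect_equal(ev$parent, sc$truth$parent)
  # acyclicity: every parent appears before its child in event order
  seen <- eh$root
  for (r in seq_len(nrow(eh$events))) {
    expect_true(eh$events$parent[r] %in% seen)
    seen <- c(seen, eh$events$child[r])
  }
  # mechanism rules on constructed corner cases
  members <- data.frame(
    id = c("P", "C1", "C2"),
    chrom = c("chr1", "chr1", "chr9"),
    start = c(0, 10000, 5e6),
    intron_structure = c("intron_containing", "intron_containing", "intronless"),
    sequence = c(sc$members$sequence[1], sc$members$sequence[2],
                 sc$members$sequence[3]),
    stringsAsFactors = FALSE)
  eh2 <- suppressWarnings(classify_events(members, root_id = "P"))
  expect_equal(eh2$events$mechanism[eh2$events$child == "C1"], "LGD")
  expect_equal(eh2$events$mechanism[eh2$events$child == "C2"], "RT")
})

test_that("the fast-evolving KLF17/KLF18-like pair forms a clade in most replicates", {
  hits <- 0L
  n_rep <- 25L
  for (s in 1:n_rep) {
    fam <- simulate_klf_family(seed = 1000 + s)
    aln <- anchor_align(fam$regions)
    tr <- nj_tree(p_distance(aln))
    hits <- hits + is_monophyletic(tr, fam$outgroup, fam$clade)
  }
  expect_gte(hits / n_rep, 0.9)
})
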