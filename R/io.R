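#' Read and write FASTA
#'
#' Thin wrappers over Biostrings readers/writers returning plain named
#' character vectors; protein sequences are normalized on read (see
#' [protein_record()]).
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- vapply(as.character(x), normalize_protein, character(1))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_protein_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_protein_fasta
#' @param seqs Named character vector of sequences.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene table from BED or GFF3
#'
#' Coordinates are converted to the package's internal 0-based half-open
#' convention (BED already is; GFF3 is 1-based inclusive on disk). For GFF3,
#' only `gene`-type records are kept and ids come from the `ID` (or `Name`)
#' attribute.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param genome_id Genome label for the resulting [gene_table()].
#' @param format `"bed"`, `"gff3"`, or `"auto"`.
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path, genome_id, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3" && "type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  ids <- if (format == "bed") gr$name else {
    id <- gr$ID
    if (is.null(id)) id <- gr$Name
    as.character(id)
  }
  feats <- data.frame(gene_id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  gene_table(genome_id, feats)
}

#' @rdname read_gene_table
#' @param table A [gene_table()].
#' @export
write_gene_table <- function(table, path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  f <- table$features
  gr <- GenomicRanges::GRanges(f$chrom,
                               IRanges::IRanges(start = f$start + 1L, end = f$end),
                               strand = f$strand)
  if (format == "bed") {
    gr$name <- f$gene_id
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$type <- "gene"
    gr$ID <- f$gene_id
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Write locus models as GFF3
#'
#' One `gene` record per scanned copy with a `status` attribute, plus `exon`
#' records for its finger-coding segments (1-based inclusive on disk).
#'
#' @param copies Output of [scan_interval_copies()].
#' @param chrom Chromosome name the copy coordinates refer to.
#' @param offset 0-based offset of the scanned interval on that chromosome.
#' @param path Output file.
#' @param genome_id Used to form feature ids.
#' @export
write_models_gff3 <- function(copies, chrom, offset = 0L, path, genome_id = "genome") {
  rows <- list()
  for (i in seq_along(copies)) {
    cp <- copies[[i]]
    gid <- sprintf("%s_locus%d", genome_id, i)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = offset + cp$g_start + 1L, end = offset + cp$g_end,
      strand = cp$strand, type = "gene", ID = gid, Parent = NA_character_,
      status = cp$status, stringsAsFactors = FALSE)
    for (j in seq_along(cp$model$segments)) {
      seg <- cp$model$segments[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = offset + seg$g_start + 1L, end = offset + seg$g_end,
        strand = seg$strand, type = "exon", ID = sprintf("%s.exon%d", gid, j),
        Parent = gid, status = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$type; gr$ID <- df$ID
  gr$Parent <- df$Parent; gr$status <- df$status
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write / read tab-separated tables
#'
#' @param x data.frame.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a position-frequency matrix file
#'
#' Tab-separated: rows are motif-segment positions, columns the 20 residues,
#' plus an information-content column in bits.
#'
#' @param pfm A `repeat_pfm` from [build_pfm()].
#' @param path File path.
#' @export
write_pfm <- function(pfm, path) {
  df <- as.data.frame(pfm$counts)
  df <- cbind(position = seq_len(nrow(df)), df,
              information_bits = round(pfm$info, 4))
  write_tsv(df, path)
}
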