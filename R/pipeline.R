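#' Pipeline configuration
#'
#' All tunables of the discovery pipeline in one round-trippable object:
#' grammar parameters, anchor lists, interval/pairing thresholds, the
#' duplication-locality threshold, and the master seed from which every stage
#' derives its own substream.
#'
#' @param grammar A [grammar_params()].
#' @param anchors Anchor gene lists, default [klf_anchor_genes()].
#' @param max_interval_bp Maximum anchored-interval span (default 1e6).
#' @param pair_window_bp Exon-pairing window for gene-model assembly
#'   (default 20000).
#' @param cluster_gap_bp Leftover-fragment clustering gap for copy
#'   separation (default 1000).
#' @param locality_bp Local-duplication threshold for event classification
#'   (default 250000).
#' @param seed Master RNG seed (default 1).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grammar = grammar_params(),
                            anchors = klf_anchor_genes(),
                            max_interval_bp = 1e6,
                            pair_window_bp = 20000L,
                            cluster_gap_bp = 1000L,
                            locality_bp = 250000L,
                            seed = 1L) {
  structure(list(grammar = grammar, anchors = anchors,
                 max_interval_bp = max_interval_bp,
                 pair_window_bp = pair_window_bp,
                 cluster_gap_bp = cluster_gap_bp,
                 locality_bp = locality_bp,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$grammar <- unclass(x$grammar)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(grammar = do.call(grammar_params, x$grammar),
                  anchors = x$anchors,
                  max_interval_bp = x$max_interval_bp,
                  pair_window_bp = x$pair_window_bp,
                  cluster_gap_bp = x$cluster_gap_bp,
                  locality_bp = x$locality_bp,
                  seed = x$seed)
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the discovery pipeline over a set of genomes
#'
#' Executes the stages in order for every genome: anchored-locus finding,
#' six-frame translated scan of the interval with gene-model assembly and
#' status calling, repeat-region detection, signature classification of the
#' recovered finger peptides, and the cross-genome presence matrix. All
#' machine outputs are written to `out_dir` (presence matrix and locus report
#' as TSV, gene models as GFF3, signatures as TSV) together with a JSON run
#' manifest (tool version, config digest, input digests, record counts).
#'
#' @param genomes Named list: genome id to named character vector of
#'   chromosome sequences.
#' @param tables Named list of [gene_table()]s, same names as `genomes`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `presence` (data.frame), `loci`,
#'   `signatures`, `copies` (per genome), and `manifest`.
#' @export
run_pipeline <- function(genomes, tables, config = pipeline_config(), out_dir) {
  if (!length(genomes)) stop("empty input set: no genomes")
  stopifnot(setequal(names(genomes), names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); loci_rows <- list(); sig_rows <- list(); copies_all <- list()
  for (gid in names(genomes)) {
    message("[synteny] ", gid)
    locus <- find_anchored_interval(tables[[gid]],
                                    upstream = config$anchors$upstream,
                                    downstream = config$anchors$downstream,
                                    max_span = config$max_interval_bp)
    statuses <- character(0); rep_found <- FALSE; copies <- list()
    if (locus_found(locus)) {
      interval <- substring(genomes[[gid]][[locus$chrom]], locus$start + 1L, locus$end)
      message("[locus_scan] ", gid, " ", locus$chrom, ":", locus$start, "-", locus$end)
      copies <- scan_interval_copies(interval, config$grammar,
                                     cluster_gap = config$cluster_gap_bp,
                                     pair_window = config$pair_window_bp)
      statuses <- vapply(copies, `[[`, character(1), "status")
      rep_found <- detect_repeat_region(interval)
      write_models_gff3(copies, locus$chrom, offset = locus$start,
                        path = file.path(out_dir, paste0(gid, "_models.gff3")),
                        genome_id = gid)
      for (i in seq_along(copies)) {
        sig <- classify_protein(model_peptide(copies[[i]]$model, interval),
                                config$grammar)
        sig_rows[[length(sig_rows) + 1L]] <- data.frame(
          genome_id = gid, copy = i, label = sig$label,
          cys_gaps = paste(sig$cys_gaps, collapse = ","),
          status = copies[[i]]$status, stringsAsFactors = FALSE)
      }
    }
    loci_rows[[length(loci_rows) + 1L]] <- data.frame(
      genome_id = gid,
      locus_found = locus_found(locus),
      chrom = if (locus_found(locus)) locus$chrom else NA_character_,
      start = if (locus_found(locus)) locus$start else NA_real_,
      end = if (locus_found(locus)) locus$end else NA_real_,
      n_upstream_anchors = if (locus_found(locus)) length(locus$upstream_found) else 0L,
      n_downstream_anchors = if (locus_found(locus)) length(locus$downstream_found) else 0L,
      stringsAsFactors = FALSE)
    results[[gid]] <- list(genome_id = gid, locus_found = locus_found(locus),
                           statuses = statuses, repeat_region_found = rep_found)
    copies_all[[gid]] <- copies
  }
  presence <- build_presence_matrix(results)
  loci <- do.call(rbind, loci_rows)
  signatures <- if (length(sig_rows)) do.call(rbind, sig_rows) else
    data.frame(genome_id = character(0), copy = integer(0), label = character(0),
               cys_gaps = character(0), status = character(0))
  write_tsv(presence, file.path(out_dir, "presence_matrix.tsv"))
  write_tsv(loci, file.path(out_dir, "loci.tsv"))
  write_tsv(signatures, file.path(out_dir, "signatures.tsv"))
  manifest <- list(
    tool = "klfscout",
    version = as.character(utils::packageVersion("klfscout")),
    config_md5 = config_digest(config),
    input_md5 = vapply(names(genomes), function(g) {
      md5_string(paste(genomes[[g]], collapse = "\n"))
    }, character(1)),
    n_genomes = length(genomes),
    n_loci_found = sum(loci$locus_found),
    n_copies = sum(presence$n_copies),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(presence = presence, loci = loci, signatures = signatures,
                 copies = copies_all, manifest = manifest))
}
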