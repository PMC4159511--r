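#' Scan TSS-upstream windows of a gene set
#'
#' Runs the full APS/motif/CPS scan over the oriented upstream window of
#' every gene (or a subset), mapping all hits back to 1-based genomic
#' coordinates. Each gene's window is scanned independently, even where
#' windows of neighbouring genes overlap. Motif orientation is reported
#' relative to the gene-sense strand: a `forward` motif lies on the coding
#' strand of the downstream gene.
#'
#' @param genome named [Biostrings::DNAStringSet] or path to a FASTA file
#' @param genes data.frame of gene records (see [read_genes()]) or path to a
#'   GFF3 file
#' @param table an [ape_table()]; default the packaged table
#' @param config a [scan_config()]
#' @param gene_ids optional character vector restricting the scan
#' @return an object of class `genome_scan`: list with `results` (one row
#'   per CPS; columns `gene_id`, `gene_name`, `seqid`, `strand`, `tss`,
#'   `aps_start`, `aps_end` (APS span incl. flanks), `run_length`,
#'   `motif_start`, `motif_end`, `matched_text`, `orientation`, `gap`,
#'   `cps_start`, `cps_end`, genomic 1-based, ordered by seqid, tss,
#'   cps_start), `aps` and `motifs` (per-gene hits in genomic coordinates),
#'   and `gene_scans` (per-gene list of region + region_scan for track
#'   export)
#' @export
scan_genes <- function(genome, genes, table = default_ape_table(),
                       config = scan_config(), gene_ids = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.character(genes)) genes <- read_genes(genes)
  if (!is.null(gene_ids)) genes <- genes[genes$gene_id %in% gene_ids, , drop = FALSE]
  rows <- list(); aps_all <- list(); motif_all <- list(); gene_scans <- list()
  for (i in seq_len(nrow(genes))) {
    gene <- genes[i, , drop = FALSE]
    region <- upstream_region(gene, config$genegap, genome)
    rs <- scan_region(region$oriented_sequence, table, config)
    gene_scans[[gene$gene_id]] <- list(region = region, scan = rs)
    gene_tss <- tss(gene)
    if (nrow(rs$aps)) {
      a <- hits_to_genome(region, rs$aps)
      a <- cbind(gene_id = gene$gene_id, a)
      aps_all[[length(aps_all) + 1L]] <- a
    }
    if (nrow(rs$motifs)) {
      m <- hits_to_genome(region, rs$motifs)
      m <- cbind(gene_id = gene$gene_id, m)
      motif_all[[length(motif_all) + 1L]] <- m
    }
    if (nrow(rs$cps)) {
      cg <- hits_to_genome(region, rs$cps)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene$gene_id, gene_name = gene$gene_name,
        seqid = gene$seqid, strand = gene$strand, tss = gene_tss,
        aps_start = cg$genomic_aps_span_start,
        aps_end = cg$genomic_aps_span_end,
        run_length = cg$run_length,
        motif_start = cg$genomic_motif_start,
        motif_end = cg$genomic_motif_end,
        matched_text = cg$matched_text,
        orientation = cg$orientation,
        gap = cg$gap,
        cps_start = cg$genomic_cps_start,
        cps_end = cg$genomic_cps_end)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene_id = character(0), gene_name = character(0), seqid = character(0),
    strand = character(0), tss = integer(0), aps_start = integer(0),
    aps_end = integer(0), run_length = integer(0), motif_start = integer(0),
    motif_end = integer(0), matched_text = character(0),
    orientation = character(0), gap = integer(0), cps_start = integer(0),
    cps_end = integer(0))
  results <- results[order(results$seqid, results$tss, results$cps_start,
                           results$motif_start), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(
    results = results,
    aps = if (length(aps_all)) do.call(rbind, aps_all) else NULL,
    motifs = if (length(motif_all)) do.call(rbind, motif_all) else NULL,
    gene_scans = gene_scans,
    config = config,
    table_source = table$source_name),
    class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  n_aps <- if (is.null(x$aps)) 0L else nrow(x$aps)
  n_mot <- if (is.null(x$motifs)) 0L else nrow(x$motifs)
  cat(sprintf(
    "genome scan of %d gene window(s): %d APS, %d motif hits, %d CPS rows\n",
    length(x$gene_scans), n_aps, n_mot, nrow(x$results)))
  invisible(x)
}
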