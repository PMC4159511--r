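#' Read a genome FASTA into a named DNAStringSet
#'
#' FASTA description lines are trimmed to their first whitespace-separated
#' word so sequence names match GFF3 seqids.
#'
#' @param path path to a (multi-)FASTA file
#' @return a [Biostrings::DNAStringSet] named by contig
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene records from a GFF3 file
#'
#' Parses the annotation with [rtracklayer::import()] and keeps features of
#' the requested type. The gene identifier is taken from the `ID` attribute
#' and the optional display name from `Name`; both attribute keys are
#' configurable. Features without an identifier, or without an explicit
#' strand, are skipped with a warning. Coordinates remain 1-based inclusive
#' as in GFF3.
#'
#' @param gff3_path path to a GFF3 (version 3) file
#' @param feature_type feature type(s) to keep (default `"gene"`)
#' @param id_attr,name_attr attribute keys for gene id and name
#' @return data.frame with columns `gene_id`, `gene_name` (`NA` when
#'   absent), `seqid`, `start`, `end`, `strand`
#' @export
read_genes <- function(gff3_path, feature_type = "gene",
                       id_attr = "ID", name_attr = "Name") {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr)) gr <- gr[as.character(gr$type) %in% feature_type]
  if (!length(gr)) {
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      seqid = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  mc <- S4Vectors::mcols(gr)
  ids <- if (id_attr %in% colnames(mc)) as.character(mc[[id_attr]]) else
    rep(NA_character_, length(gr))
  nms <- if (name_attr %in% colnames(mc)) as.character(mc[[name_attr]]) else
    rep(NA_character_, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  drop <- is.na(ids) | !nzchar(ids)
  if (any(drop)) {
    warning(sum(drop), " feature(s) without an '", id_attr,
            "' attribute skipped")
  }
  bad_strand <- !drop & !(strand %in% c("+", "-"))
  if (any(bad_strand)) {
    warning(sum(bad_strand), " feature(s) without an explicit strand skipped")
    drop <- drop | bad_strand
  }
  keep <- which(!drop)
  data.frame(
    gene_id = ids[keep], gene_name = nms[keep],
    seqid = as.character(GenomeInfoDb::seqnames(gr))[keep],
    start = BiocGenerics::start(gr)[keep],
    end = BiocGenerics::end(gr)[keep],
    strand = strand[keep])
}

#' Transcription start site of a gene record
#'
#' The TSS is approximated by the 5' end of the gene feature: `start` for
#' plus-strand genes, `end` for minus-strand genes.
#'
#' @param gene data.frame of gene records (as from [read_genes()])
#' @return integer vector of 1-based genomic TSS coordinates
#' @export
tss <- function(gene) {
  ifelse(gene$strand == "+", gene$start, gene$end)
}

#' Extract the oriented upstream window of a gene
#'
#' Returns the `genegap` bases strictly 5' of the TSS, excluding the TSS
#' base itself, as a sequence oriented in the gene's 5'->3' sense (so a
#' motif on the coding strand reads forward). Windows are clipped at contig
#' edges; a TSS at the contig edge yields a zero-length region.
#'
#' @param gene one gene record (1-row data.frame)
#' @param genegap upstream window size in bp
#' @param genome named [Biostrings::DNAStringSet] (or named character vector)
#' @return an `upstream_region`: list with the `gene` row, `seqid`,
#'   `strand`, 1-based inclusive `genomic_start`/`genomic_end`, and
#'   `oriented_sequence`; oriented position 0 is the window base farthest
#'   from the TSS
#' @export
upstream_region <- function(gene, genegap, genome) {
  stopifnot(nrow(gene) == 1L)
  genegap <- as.integer(genegap)
  if (is.na(genegap) || genegap < 1L) stop("`genegap` must be a positive integer")
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!(gene$seqid %in% names(genome))) {
    stop("contig '", gene$seqid, "' not present in genome")
  }
  contig_len <- Biostrings::width(genome[gene$seqid])
  if (gene$strand == "+") {
    gstart <- max(1L, gene$start - genegap)
    gend <- gene$start - 1L
  } else {
    gstart <- gene$end + 1L
    gend <- min(contig_len, gene$end + genegap)
  }
  if (gend < gstart) {
    seq <- ""
    gstart <- 1L
    gend <- 0L
  } else {
    seq <- as.character(Biostrings::subseq(genome[[gene$seqid]], gstart, gend))
    if (gene$strand == "-") seq <- revcomp(seq)
  }
  structure(list(gene = gene, seqid = gene$seqid, strand = gene$strand,
                 genomic_start = as.integer(gstart),
                 genomic_end = as.integer(gend),
                 oriented_sequence = toupper(seq)),
            class = "upstream_region")
}

#' Map oriented region positions to genomic coordinates
#'
#' @param region an [upstream_region()]
#' @param pos 0-based positions in the oriented sequence
#' @return 1-based genomic coordinates
#' @export
oriented_to_genomic <- function(region, pos) {
  stopifnot(inherits(region, "upstream_region"))
  L <- nchar(region$oriented_sequence)
  if (any(pos < 0L, na.rm = TRUE) || any(pos > L - 1L, na.rm = TRUE)) {
    stop("oriented position out of range for region")
  }
  if (region$strand == "+") region$genomic_start + as.integer(pos)
  else region$genomic_end - as.integer(pos)
}

#' Map genomic coordinates back to oriented region positions
#' @param region an [upstream_region()]
#' @param gpos 1-based genomic coordinates inside the region
#' @return 0-based oriented positions
#' @export
genomic_to_oriented <- function(region, gpos) {
  stopifnot(inherits(region, "upstream_region"))
  if (any(gpos < region$genomic_start, na.rm = TRUE) ||
      any(gpos > region$genomic_end, na.rm = TRUE)) {
    stop("genomic position outside region")
  }
  if (region$strand == "+") as.integer(gpos) - region$genomic_start
  else region$genomic_end - as.integer(gpos)
}

# column pairs understood by hits_to_genome, in oriented 0-based coordinates
.hit_coord_pairs <- list(
  c("start", "end"),
  c("run_start", "run_end"),
  c("span_start", "span_end"),
  c("cps_start", "cps_end"),
  c("aps_run_start", "aps_run_end"),
  c("aps_span_start", "aps_span_end"),
  c("motif_start", "motif_end"))

#' Map scan hits from oriented region coordinates to genome coordinates
#'
#' For every recognised pair of oriented 0-based coordinate columns in
#' `hits` (e.g. `start`/`end`, `span_start`/`span_end`,
#' `cps_start`/`cps_end`), appends 1-based genomic columns prefixed
#' `genomic_` with `genomic_* start <= end` guaranteed: coordinates of
#' minus-strand regions are reflected. The original oriented columns are
#' retained.
#'
#' @param region an [upstream_region()]
#' @param hits data.frame of hits in oriented coordinates
#' @return `hits` with appended genomic coordinate columns plus `seqid` and
#'   `region_strand`
#' @export
hits_to_genome <- function(region, hits) {
  stopifnot(inherits(region, "upstream_region"), is.data.frame(hits))
  out <- hits
  for (pair in .hit_coord_pairs) {
    if (!all(pair %in% names(hits))) next
    a <- oriented_to_genomic(region, hits[[pair[1]]])
    b <- oriented_to_genomic(region, hits[[pair[2]]])
    out[[paste0("genomic_", pair[1])]] <- pmin(a, b)
    out[[paste0("genomic_", pair[2])]] <- pmax(a, b)
  }
  if (nrow(out)) {
    out$seqid <- region$seqid
    out$region_strand <- region$strand
  } else {
    out$seqid <- character(0)
    out$region_strand <- character(0)
  }
  out
}
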