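#' Write the CPS results table
#'
#' One tab-separated row per combined promoter sequence, listing the APS and
#' motif positions and summary details of the corresponding gene. Columns
#' (genomic coordinates 1-based inclusive): `gene_id`, `gene_name`, `seqid`,
#' `strand`, `tss`, `aps_start`, `aps_end` (APS span including flanks),
#' `run_length`, `motif_start`, `motif_end`, `matched_text`, `orientation`
#' (relative to the gene sense), `gap`, `cps_start`, `cps_end`. Rows are
#' ordered by seqid, tss, cps_start.
#'
#' @param rows a `genome_scan` or its `results` data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_results_tsv <- function(rows, path) {
  if (inherits(rows, "genome_scan")) rows <- rows$results
  stopifnot(is.data.frame(rows))
  rows <- rows[order(rows$seqid, rows$tss, rows$cps_start, rows$motif_start), ,
               drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

bed_line <- function(seqid, start1, end1, name, score = 0, strand = ".") {
  sprintf("%s\t%d\t%d\t%s\t%d\t%s", seqid, start1 - 1L, end1, name, score,
          strand)
}

# genome strand of a motif hit: gene-sense forward means the motif lies on
# the gene's strand
motif_genome_strand <- function(orientation, region_strand) {
  ifelse(orientation == "forward", region_strand,
         ifelse(region_strand == "+", "-", "+"))
}

#' Write BED annotation tracks for a genome scan
#'
#' Produces three BED files (0-based half-open intervals, each with a track
#' line): `<prefix>.aps.bed` with the APS spans, `<prefix>.motif.bed` with
#' the motif hits (strand column gives the genome strand the motif text lies
#' on), and `<prefix>.apesign.bed` segmenting every search region into
#' constant-sign APE stretches labelled `neg`, `pos` (zero counts as pos) or
#' `undet`, tiling the region without gaps or overlaps.
#'
#' @param scan a `genome_scan` from [scan_genes()]
#' @param prefix output path prefix
#' @return named character vector of the three file paths, invisibly
#' @export
write_bed <- function(scan, prefix) {
  stopifnot(inherits(scan, "genome_scan"))
  aps_path <- paste0(prefix, ".aps.bed")
  motif_path <- paste0(prefix, ".motif.bed")
  sign_path <- paste0(prefix, ".apesign.bed")

  aps_lines <- 'track name="APS" description="A-form promoter sequences (span incl. flanks)"'
  if (!is.null(scan$aps) && nrow(scan$aps)) {
    a <- scan$aps[order(scan$aps$seqid, scan$aps$genomic_span_start,
                        scan$aps$gene_id), , drop = FALSE]
    aps_lines <- c(aps_lines, bed_line(
      a$seqid, a$genomic_span_start, a$genomic_span_end,
      sprintf("%s_APS%d", a$gene_id, seq_len(nrow(a))), 0, "."))
  }
  writeLines(aps_lines, aps_path)

  motif_lines <- 'track name="motifs" description="promoter motif hits"'
  if (!is.null(scan$motifs) && nrow(scan$motifs)) {
    m <- scan$motifs[order(scan$motifs$seqid, scan$motifs$genomic_start,
                           scan$motifs$gene_id, scan$motifs$source_motif), ,
                     drop = FALSE]
    motif_lines <- c(motif_lines, bed_line(
      m$seqid, m$genomic_start, m$genomic_end,
      sprintf("%s_%s", m$gene_id, m$matched_text), 0,
      motif_genome_strand(m$orientation, m$region_strand)))
  }
  writeLines(motif_lines, motif_path)

  sign_lines <- 'track name="APE_sign" description="sign of the APE values over search regions"'
  for (gid in names(scan$gene_scans)) {
    gs <- scan$gene_scans[[gid]]
    seg <- ape_sign_segments(gs$region, gs$scan$profile)
    if (nrow(seg)) {
      sign_lines <- c(sign_lines, bed_line(
        seg$seqid, seg$start, seg$end, paste0(gid, "_", seg$label), 0, "."))
    }
  }
  writeLines(sign_lines, sign_path)
  invisible(c(aps = aps_path, motif = motif_path, apesign = sign_path))
}

# segment a region's profile into constant-sign stretches in genomic order;
# returns 1-based inclusive genomic intervals tiling the region
ape_sign_segments <- function(region, profile) {
  L <- length(profile$values)
  if (L == 0L) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), label = character(0)))
  }
  label <- ifelse(!profile$determined, "undet",
                  ifelse(profile$values < 0, "neg", "pos"))
  if (region$strand == "-") label <- rev(label)  # genomic left-to-right
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(seqid = region$seqid,
             start = region$genomic_start + starts - 1L,
             end = region$genomic_start + ends - 1L,
             label = r$values)
}

#' Write a WIG track of APE scores over the search regions
#'
#' Emits fixedStep (step 1, span 1, 1-based) blocks of the per-base APE
#' values in genomic coordinate order. Undetermined positions are omitted:
#' each maximal stretch of determined positions becomes its own fixedStep
#' block, so no sentinel values distort browser scaling. Because APE sums
#' both strands, values are strand-independent and are written on the
#' genomic forward coordinate.
#'
#' @param scan a `genome_scan` from [scan_genes()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_wig <- function(scan, path) {
  stopifnot(inherits(scan, "genome_scan"))
  lines <- 'track type=wiggle_0 name="APE" description="A-DNA propensity energy (kcal/mol)"'
  for (gid in names(scan$gene_scans)) {
    gs <- scan$gene_scans[[gid]]
    prof <- gs$scan$profile
    L <- length(prof$values)
    if (L == 0L) next
    vals <- prof$values
    det <- prof$determined
    if (gs$region$strand == "-") { vals <- rev(vals); det <- rev(det) }
    r <- rle(det)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      gstart <- gs$region$genomic_start + starts[k] - 1L
      lines <- c(lines,
                 sprintf("fixedStep chrom=%s start=%d step=1 span=1",
                         gs$region$seqid, gstart),
                 as.character(vals[starts[k]:ends[k]]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write scan results as GFF3 features
#'
#' Each CPS row becomes three GFF3 feature lines sharing an ID/Parent
#' linkage: a `CPS` feature spanning from the APS span start to the motif
#' end, with child `APS` and `motif` features. Coordinates are 1-based
#' inclusive; attributes carry the gene id, gap and motif orientation.
#'
#' @param rows a `genome_scan` or its `results` data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff <- function(rows, path) {
  if (inherits(rows, "genome_scan")) rows <- rows$results
  stopifnot(is.data.frame(rows))
  rows <- rows[order(rows$seqid, rows$tss, rows$cps_start, rows$motif_start), ,
               drop = FALSE]
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    id <- sprintf("cps%05d", i)
    lines <- c(lines,
      sprintf("%s\tapescan\tCPS\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gap=%d;orientation=%s",
              r$seqid, r$cps_start, r$cps_end, r$strand, id, r$gene_id,
              r$gap, r$orientation),
      sprintf("%s\tapescan\tAPS\t%d\t%d\t.\t%s\t.\tID=%s.aps;Parent=%s;gene_id=%s;run_length=%d",
              r$seqid, r$aps_start, r$aps_end, r$strand, id, id, r$gene_id,
              r$run_length),
      sprintf("%s\tapescan\tmotif\t%d\t%d\t.\t%s\t.\tID=%s.motif;Parent=%s;gene_id=%s;orientation=%s;matched_text=%s",
              r$seqid, r$motif_start, r$motif_end,
              motif_genome_strand(r$orientation, r$strand), id, id,
              r$gene_id, r$orientation, r$matched_text))
  }
  writeLines(lines, path)
  invisible(path)
}
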