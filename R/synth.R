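#' Specification for a synthetic genome with planted elements
#'
#' Describes a test genome: genes alternating between strands along one
#' contig, each with a `genegap`-sized upstream window of background
#' sequence at the given base composition, optionally carrying a planted
#' A-form element. Plants are G-runs on the gene-sense strand (negative
#' under the packaged table's interior triplets and under the `gc_negative`
#' test table, whose central-base rule makes every G/C-centred position
#' negative); `cps` plants add a motif at a controlled gap downstream of
#' the run. Background windows that would create an unplanned G/C run of
#' `apelen` or more, or an unplanned motif occurrence, are resampled so the
#' truth table is exact under the `gc_negative` table.
#'
#' @param n_genes number of genes
#' @param directives character vector recycled over genes: `"none"`,
#'   `"aps_only"` or `"cps"`
#' @param motif,gap,aps_run_length,orientation,offset_from_tss plant
#'   parameters, recycled over genes: motif text, bases strictly between the
#'   APS span and the motif (0..`motifgap`), length of the planted G-run,
#'   motif orientation (`forward`/`reverse_complement`) relative to the gene
#'   sense, and bases between the motif end and the TSS (`NA` = random
#'   placement)
#' @param frequencies background A/C/G/T composition
#' @param genegap,apelen,motifgap scan parameters the plants are guaranteed
#'   against (see [scan_config()])
#' @param gene_length,pad gene body length and inter-slot padding, bp
#' @param scan_motifs full motif set the windows are protected against
#'   (unplanned occurrences of any of these near a run are resampled);
#'   planted motifs are always included
#' @param seed integer seed; generation is deterministic given the spec
#' @return a `plant_spec` list with a per-gene `directives` data.frame
#' @export
plant_spec <- function(n_genes = 6L, directives = "cps", motif = "CCAAT",
                       gap = 5L, aps_run_length = 12L,
                       orientation = "forward", offset_from_tss = NA,
                       frequencies = c(0.3, 0.2, 0.2, 0.3),
                       genegap = 500L, apelen = 10L, motifgap = 20L,
                       gene_length = 100L, pad = 50L,
                       scan_motifs = c("CCAAT", "GGGCGG", "AGATA", "TGATA"),
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 0L) stop("`n_genes` must be >= 0")
  frequencies <- check_frequencies(frequencies)
  d <- data.frame(
    directive = rep_len(as.character(directives), max(n_genes, 1L)),
    motif = rep_len(toupper(motif), max(n_genes, 1L)),
    gap = rep_len(as.integer(gap), max(n_genes, 1L)),
    aps_run_length = rep_len(as.integer(aps_run_length), max(n_genes, 1L)),
    orientation = rep_len(as.character(orientation), max(n_genes, 1L)),
    offset_from_tss = rep_len(as.integer(offset_from_tss), max(n_genes, 1L)))
  d <- d[seq_len(n_genes), , drop = FALSE]
  if (!all(d$directive %in% c("none", "aps_only", "cps"))) {
    stop("directives must be 'none', 'aps_only' or 'cps'")
  }
  if (!all(d$orientation %in% c("forward", "reverse_complement"))) {
    stop("orientation must be 'forward' or 'reverse_complement'")
  }
  if (any(d$gap < 0L) || any(d$gap > motifgap)) {
    stop("planted `gap` must lie in [0, motifgap]")
  }
  if (any(d$aps_run_length < apelen)) {
    stop("planted `aps_run_length` must be >= apelen")
  }
  need <- 1L + d$aps_run_length + d$gap + 1L + nchar(d$motif) + 1L
  if (any(d$directive == "cps" & need > genegap)) {
    stop("plant does not fit inside the upstream window")
  }
  structure(list(n_genes = n_genes, directives = d,
                 scan_motifs = toupper(scan_motifs),
                 frequencies = frequencies, genegap = as.integer(genegap),
                 apelen = as.integer(apelen), motifgap = as.integer(motifgap),
                 gene_length = as.integer(gene_length), pad = as.integer(pad),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# random A/T-only filler (never extends a G/C run, never part of an ACGT motif
# containing G or C)
at_filler <- function(n) {
  if (n == 0L) return("")
  paste(c("A", "T")[findInterval(stats::runif(n), 0.5) + 1L], collapse = "")
}

# assemble one oriented upstream window; returns list(seq, truth row or NULL)
build_window <- function(dir_row, spec, all_motifs, max_tries = 200L) {
  genegap <- spec$genegap
  r <- dir_row$aps_run_length
  has_plant <- dir_row$directive %in% c("aps_only", "cps")
  has_motif <- dir_row$directive == "cps"
  motif_txt <- if (has_motif) {
    if (dir_row$orientation == "forward") dir_row$motif else revcomp(dir_row$motif)
  } else ""
  plant_len <- if (has_plant) {
    1L + r + if (has_motif) dir_row$gap + 1L + nchar(motif_txt) + 1L else 2L
  } else 0L
  for (try in seq_len(max_tries)) {
    bg <- random_sequence(spec$frequencies, genegap)
    truth <- NULL
    win <- bg
    if (has_plant) {
      # choose run start o (0-based oriented); need o >= 1 and plant inside window
      if (has_motif && !is.na(dir_row$offset_from_tss)) {
        motif_end <- genegap - 1L - dir_row$offset_from_tss
        o <- motif_end - nchar(motif_txt) + 1L - dir_row$gap - 1L - r
        if (o < 1L || motif_end > genegap - 1L) {
          stop("plant does not fit inside the upstream window at the requested offset")
        }
      } else {
        o_max <- genegap - plant_len + 1L  # plant segment starts at o - 1
        if (o_max < 1L) stop("plant does not fit inside the upstream window")
        o <- 1L + as.integer(floor(stats::runif(1) * o_max))
      }
      seg <- if (has_motif) {
        paste0("A", strrep("G", r), at_filler(dir_row$gap + 1L), motif_txt, "A")
      } else {
        paste0("A", strrep("G", r), "A")
      }
      s0 <- o - 1L  # 0-based segment start (flank base before the run)
      win <- paste0(substr(bg, 1L, s0), seg,
                    substr(bg, s0 + nchar(seg) + 1L, genegap))
      run_start <- o
      run_end <- o + r - 1L
      truth <- data.frame(
        directive = dir_row$directive,
        run_start = run_start, run_end = run_end,
        span_start = run_start - 1L, span_end = run_end + 1L,
        motif_start = if (has_motif) run_end + 2L + dir_row$gap else NA_integer_,
        motif_end = if (has_motif) run_end + 2L + dir_row$gap + nchar(motif_txt) - 1L
                    else NA_integer_,
        matched_text = if (has_motif) motif_txt else NA_character_,
        source_motif = if (has_motif) dir_row$motif else NA_character_,
        orientation = if (has_motif) dir_row$orientation else NA_character_,
        gap = if (has_motif) dir_row$gap else NA_integer_,
        cps_start = if (has_motif) run_start - 1L else NA_integer_,
        cps_end = if (has_motif) run_end + 2L + dir_row$gap + nchar(motif_txt) - 1L
                  else NA_integer_)
    }
    if (window_clean(win, truth, spec, all_motifs)) {
      return(list(seq = win, truth = truth))
    }
  }
  stop("failed to generate a collision-free window in ", max_tries, " tries")
}

# TRUE when the assembled window contains exactly the planted elements:
# no unplanned maximal G/C run >= apelen, and no motif occurrence creating a
# CPS other than the planted one
window_clean <- function(win, truth, spec, all_motifs) {
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  s <- ch %in% c("G", "C")
  s[c(1L, length(s))] <- FALSE  # profile ends are undetermined
  rl <- rle(s)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  runs <- which(rl$values & rl$lengths >= spec$apelen)
  run_iv <- cbind(starts[runs] - 1L, ends[runs] - 1L)  # 0-based
  if (is.null(truth)) {
    if (nrow(run_iv)) return(FALSE)
  } else {
    want <- if (truth$directive %in% c("aps_only", "cps")) {
      cbind(truth$run_start, truth$run_end)
    } else {
      matrix(integer(0), ncol = 2)
    }
    if (!identical(unname(run_iv), unname(want))) return(FALSE)
  }
  # motif occurrences within coupling distance of any qualifying run
  hits <- find_motifs(win, all_motifs)
  for (k in seq_len(nrow(run_iv))) {
    span_end <- run_iv[k, 2] + 1L
    near <- hits$start > span_end & hits$start <= span_end + 1L + spec$motifgap
    planted <- if (!is.null(truth) && !is.na(truth$motif_start)) {
      hits$start == truth$motif_start & hits$matched_text == truth$matched_text
    } else {
      rep(FALSE, nrow(hits))
    }
    if (is.null(truth) || is.na(truth$motif_start)) {
      if (any(near)) return(FALSE)           # would create an unplanned CPS
    } else {
      if (!any(near & planted)) return(FALSE)
      if (any(near & !planted)) return(FALSE)
    }
  }
  TRUE
}

#' Generate a synthetic genome with planted APS/CPS elements
#'
#' Builds a single-contig genome whose genes alternate between the plus and
#' minus strand, writes it as FASTA plus GFF3, and returns a truth table of
#' all planted elements in both oriented and genomic coordinates. Scanning
#' the emitted files with the matching parameters and the `gc_negative`
#' test table recovers exactly the planted CPS.
#'
#' @param spec a [plant_spec()]
#' @param dir output directory (created if needed); default a fresh tempdir
#' @param basename file basename for the FASTA/GFF3/truth files
#' @return list with `fasta`, `gff3`, `truth_tsv` (paths), `genome`
#'   (DNAStringSet), `genes` (gene record data.frame) and `truth`
#'   (data.frame: per planted gene the oriented and genomic coordinates of
#'   the run, span, motif and CPS, with `genomic_*` columns 1-based)
#' @export
make_synthetic_genome <- function(spec, dir = tempfile("synthgenome"),
                                  basename = "synthetic") {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  all_motifs <- unique(c(
    spec$scan_motifs,
    spec$directives$motif[spec$directives$directive == "cps"]))
  pieces <- character(0)
  genes <- list()
  windows <- list()
  cursor <- 1L  # 1-based genomic position of the next piece
  for (i in seq_len(spec$n_genes)) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    w <- build_window(spec$directives[i, , drop = FALSE], spec, all_motifs)
    body <- random_sequence(spec$frequencies, spec$gene_length)
    pad <- random_sequence(spec$frequencies, spec$pad)
    if (strand == "+") {
      # pad | window (as-is) | gene body
      gene_start <- cursor + spec$pad + spec$genegap
      pieces <- c(pieces, pad, w$seq, body)
    } else {
      # pad | gene body | window (reverse-complemented into the genome)
      gene_start <- cursor + spec$pad
      pieces <- c(pieces, pad, body, revcomp(w$seq))
    }
    gene_end <- gene_start + spec$gene_length - 1L
    genes[[i]] <- data.frame(
      gene_id = sprintf("g%03d", i), gene_name = sprintf("synth_gene_%03d", i),
      seqid = "chrS", start = gene_start, end = gene_end, strand = strand)
    windows[[i]] <- w
    cursor <- cursor + spec$pad + spec$genegap + spec$gene_length
  }
  contig <- paste(c(pieces, random_sequence(spec$frequencies, spec$pad)),
                  collapse = "")
  if (!nzchar(contig)) contig <- random_sequence(spec$frequencies, 200L)
  genome <- Biostrings::DNAStringSet(c(chrS = contig))
  genes_df <- if (length(genes)) do.call(rbind, genes) else data.frame(
    gene_id = character(0), gene_name = character(0), seqid = character(0),
    start = integer(0), end = integer(0), strand = character(0))
  # truth in genomic coordinates via the same mapping the scanner uses
  truth <- list()
  for (i in seq_len(spec$n_genes)) {
    t <- windows[[i]]$truth
    if (is.null(t)) next
    region <- upstream_region(genes_df[i, , drop = FALSE], spec$genegap, genome)
    g <- hits_to_genome(region, t)
    g <- cbind(gene_id = genes_df$gene_id[i], strand = genes_df$strand[i],
               tss = tss(genes_df[i, , drop = FALSE]), g)
    truth[[length(truth) + 1L]] <- g
  }
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(basename, ".fa"))
  gff3 <- file.path(dir, paste0(basename, ".gff3"))
  truth_tsv <- file.path(dir, paste0(basename, ".truth.tsv"))
  Biostrings::writeXStringSet(genome, fasta)
  write_gene_gff3(genes_df, gff3)
  if (!is.null(truth_df)) {
    utils::write.table(truth_df, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste(c("gene_id", "directive"), collapse = "\t"), truth_tsv)
  }
  list(fasta = fasta, gff3 = gff3, truth_tsv = truth_tsv, genome = genome,
       genes = genes_df, truth = truth_df)
}

write_gene_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  if (nrow(genes)) {
    lines <- c(lines, sprintf(
      "%s\tapescan_synth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genes$seqid, genes$start, genes$end, genes$strand,
      genes$gene_id, genes$gene_name))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct standard test APE tables
#'
#' Three synthetic table shapes used throughout the test-suite:
#' `uniform_negative` sets every triplet to -1 (every interior ACGT position
#' scores -2); `gc_negative` sets triplets with a central G or C to -1 and
#' the rest to +1, so the negative positions of a sequence are exactly its
#' interior G/C bases; `random` draws seeded values in [-2, 2] with 14
#' randomly chosen undetermined triplets, mirroring the shape of the
#' packaged table.
#'
#' @param kind one of `"uniform_negative"`, `"gc_negative"`, `"random"`
#' @param seed seed for `kind = "random"`
#' @return an [ape_table()]
#' @export
make_test_ape_table <- function(kind = c("uniform_negative", "gc_negative",
                                         "random"), seed = 1L) {
  kind <- match.arg(kind)
  trips <- all_triplets()
  if (kind == "uniform_negative") {
    vals <- rep(-1, 64L)
  } else if (kind == "gc_negative") {
    central <- substr(trips, 2L, 2L)
    vals <- ifelse(central %in% c("G", "C"), -1, 1)
  } else {
    set.seed(as.integer(seed))
    vals <- stats::runif(64L, -2, 2)
    vals[sample.int(64L, 14L)] <- NA_real_
  }
  names(vals) <- trips
  ape_table(vals, source_name = paste0("test:", kind))
}
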