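#' Scan configuration
#'
#' Bundles the four scan parameters. Defaults are the tool's canonical
#' settings: motif CCAAT, `apelen` 10 (minimum number of consecutive
#' negative APE values in an APS, so the reported APS span including its two
#' flanking bases is at least 12 bp), `motifgap` 20 (maximum bases strictly
#' between the APS span and the motif, set by the footprint of CCAAT-box
#' binding complexes), and `genegap` 500 (bp searched upstream of each TSS).
#'
#' @param motifs character vector of promoter motifs over ACGT; each is
#'   searched in both orientations
#' @param apelen positive integer, minimum run length of negative APE values
#' @param motifgap non-negative integer, maximum APS-motif separation in bases
#' @param genegap positive integer, upstream window size in bp
#' @return a `scan_config` list
#' @export
scan_config <- function(motifs = "CCAAT", apelen = 10L, motifgap = 20L,
                        genegap = 500L) {
  motifs <- toupper(as.character(motifs))
  if (!length(motifs) || any(!nzchar(motifs)) || any(grepl("[^ACGT]", motifs))) {
    stop("`motifs` must be non-empty strings over ACGT")
  }
  apelen <- as.integer(apelen)
  motifgap <- as.integer(motifgap)
  genegap <- as.integer(genegap)
  if (is.na(apelen) || apelen < 1L) stop("`apelen` must be a positive integer")
  if (is.na(motifgap) || motifgap < 0L) stop("`motifgap` must be >= 0")
  if (is.na(genegap) || genegap < 1L) stop("`genegap` must be a positive integer")
  structure(list(motifs = motifs, apelen = apelen, motifgap = motifgap,
                 genegap = genegap),
            class = "scan_config")
}

empty_aps <- function() {
  data.frame(run_start = integer(0), run_end = integer(0),
             span_start = integer(0), span_end = integer(0),
             run_length = integer(0), min_ape = numeric(0),
             sum_ape = numeric(0))
}

empty_motifs <- function() {
  data.frame(start = integer(0), end = integer(0),
             matched_text = character(0), orientation = character(0),
             source_motif = character(0))
}

empty_cps <- function() {
  data.frame(cps_start = integer(0), cps_end = integer(0), gap = integer(0),
             aps_index = integer(0), motif_index = integer(0),
             aps_run_start = integer(0), aps_run_end = integer(0),
             aps_span_start = integer(0), aps_span_end = integer(0),
             run_length = integer(0), motif_start = integer(0),
             motif_end = integer(0), matched_text = character(0),
             orientation = character(0), source_motif = character(0))
}

#' Detect A-form promoter sequences (APS) in an APE profile
#'
#' An APS is a maximal run of consecutive positions whose APE values are
#' determined and strictly negative, of length at least `apelen`, reported
#' together with the two flanking bases its APE calculation depends on.
#' Zero values and undetermined positions terminate runs. Maximal runs only:
#' a 15-long negative run yields one hit, never nested sub-runs.
#'
#' All coordinates are 0-based inclusive positions in the profiled sequence.
#' `span_start = run_start - 1` and `span_end = run_end + 1`; since positions
#' 0 and L-1 are always undetermined, spans stay inside the sequence.
#'
#' @param profile an [ape_profile()]
#' @param apelen positive integer, minimum run length
#' @return data.frame with columns `run_start`, `run_end`, `span_start`,
#'   `span_end`, `run_length`, `min_ape`, `sum_ape`, in ascending position
#'   order
#' @export
find_aps <- function(profile, apelen) {
  stopifnot(inherits(profile, "ape_profile"))
  apelen <- as.integer(apelen)
  if (is.na(apelen) || apelen < 1L) stop("`apelen` must be >= 1")
  neg <- profile$determined & !is.na(profile$values) & profile$values < 0
  if (!any(neg)) return(empty_aps())
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= apelen
  if (!any(keep)) return(empty_aps())
  rs <- starts[keep] - 1L   # to 0-based
  re <- ends[keep] - 1L
  data.frame(
    run_start = rs, run_end = re,
    span_start = rs - 1L, span_end = re + 1L,
    run_length = re - rs + 1L,
    min_ape = vapply(seq_along(rs), function(k)
      min(profile$values[(rs[k] + 1L):(re[k] + 1L)]), numeric(1)),
    sum_ape = vapply(seq_along(rs), function(k)
      sum(profile$values[(rs[k] + 1L):(re[k] + 1L)]), numeric(1)))
}

#' Find exact motif occurrences on both orientations
#'
#' Reports every occurrence of each motif and of its reverse complement,
#' overlaps allowed, case-insensitive. For palindromic motifs each position
#' is reported once with orientation `forward`. One hit is reported per
#' (position, source motif, orientation).
#'
#' @param sequence a DNA string
#' @param motifs character vector of motifs over ACGT
#' @return data.frame with 0-based inclusive `start`, `end`, the actual
#'   `matched_text`, `orientation` (`forward` or `reverse_complement`) and
#'   `source_motif`, sorted by start, then orientation, then source motif
#' @export
find_motifs <- function(sequence, motifs) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  motifs <- toupper(motifs)
  if (any(grepl("[^ACGT]", motifs)) || any(!nzchar(motifs))) {
    stop("`motifs` must be non-empty strings over ACGT")
  }
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  subj <- if (L > 0L) Biostrings::DNAString(gsub("[^ACGT]", "N", sequence)) else NULL
  out <- list()
  for (m in unique(motifs)) {
    rc <- revcomp(m)
    pats <- if (rc == m) c(forward = m) else c(forward = m, reverse_complement = rc)
    for (orient in names(pats)) {
      pat <- pats[[orient]]
      if (is.null(subj) || nchar(pat) > L) next
      mt <- Biostrings::matchPattern(pat, subj)
      if (!length(mt)) next
      st <- BiocGenerics::start(mt) - 1L
      out[[length(out) + 1L]] <- data.frame(
        start = st, end = BiocGenerics::end(mt) - 1L,
        matched_text = pat, orientation = orient, source_motif = m)
    }
  }
  if (!length(out)) return(empty_motifs())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$orientation, res$source_motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Couple APS and motif hits into combined promoter sequences (CPS)
#'
#' A CPS is an APS followed by a motif occurrence with at most `motifgap`
#' bases strictly between the APS span end (which includes the 3' flanking
#' base) and the motif start; the motif must lie strictly downstream of the
#' APS span. Every qualifying (APS, motif) pair is a distinct CPS: one APS
#' may pair with several motifs and vice versa. The CPS extends from the
#' start of the APS span to the end of the motif.
#'
#' @param aps_hits data.frame from [find_aps()]
#' @param motif_hits data.frame from [find_motifs()]
#' @param motifgap non-negative integer
#' @return data.frame with one row per pairing: `cps_start`, `cps_end`,
#'   `gap`, indices into the input frames, and the flattened APS/motif
#'   columns; ordered by `cps_start`, then motif position, then orientation
#' @export
find_cps <- function(aps_hits, motif_hits, motifgap) {
  motifgap <- as.integer(motifgap)
  if (is.na(motifgap) || motifgap < 0L) stop("`motifgap` must be >= 0")
  if (!nrow(aps_hits) || !nrow(motif_hits)) return(empty_cps())
  pairs <- expand.grid(aps_index = seq_len(nrow(aps_hits)),
                       motif_index = seq_len(nrow(motif_hits)))
  gap <- motif_hits$start[pairs$motif_index] -
    aps_hits$span_end[pairs$aps_index] - 1L
  keep <- gap >= 0L & gap <= motifgap
  if (!any(keep)) return(empty_cps())
  pairs <- pairs[keep, , drop = FALSE]
  gap <- gap[keep]
  a <- aps_hits[pairs$aps_index, , drop = FALSE]
  m <- motif_hits[pairs$motif_index, , drop = FALSE]
  res <- data.frame(
    cps_start = a$span_start, cps_end = m$end, gap = gap,
    aps_index = pairs$aps_index, motif_index = pairs$motif_index,
    aps_run_start = a$run_start, aps_run_end = a$run_end,
    aps_span_start = a$span_start, aps_span_end = a$span_end,
    run_length = a$run_length,
    motif_start = m$start, motif_end = m$end,
    matched_text = m$matched_text, orientation = m$orientation,
    source_motif = m$source_motif)
  res <- res[order(res$cps_start, res$motif_start, res$orientation,
                   res$source_motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan one sequence for APS, motifs and CPS
#'
#' Runs the full per-region pipeline: APE profile, APS detection, motif
#' search in both orientations, and APS-motif coupling. The APS-only and
#' motif-only results are returned alongside the CPS list so callers can
#' tally elements independently of their combination.
#'
#' @param sequence a DNA string (typically a gene-sense oriented upstream
#'   window)
#' @param table an [ape_table()]
#' @param config a [scan_config()]
#' @return an object of class `region_scan`: list with elements `cps`,
#'   `aps`, `motifs` (data.frames as returned by the stage functions) and
#'   `profile` (the [ape_profile()])
#' @export
scan_region <- function(sequence, table, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (!nzchar(sequence)) {
    return(structure(list(cps = empty_cps(), aps = empty_aps(),
                          motifs = empty_motifs(),
                          profile = ape_profile(table, "")),
                     class = "region_scan"))
  }
  profile <- ape_profile(table, sequence)
  aps <- find_aps(profile, config$apelen)
  motifs <- find_motifs(sequence, config$motifs)
  cps <- find_cps(aps, motifs, config$motifgap)
  structure(list(cps = cps, aps = aps, motifs = motifs, profile = profile),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat(sprintf("region scan: %d APS, %d motif hits, %d CPS over %d bp\n",
              nrow(x$aps), nrow(x$motifs), nrow(x$cps),
              length(x$profile$values)))
  invisible(x)
}
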