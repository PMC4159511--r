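check_frequencies <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != 4L || anyNA(frequencies)) {
    stop("`frequencies` must be four numbers (A, C, G, T)")
  }
  if (any(frequencies < 0)) stop("negative nucleotide frequency")
  s <- sum(frequencies)
  if (abs(s - 1) > 1e-6) stop("frequencies must sum to 1 (got ", s, ")")
  frequencies / s
}

#' Random DNA sequence at given base composition
#'
#' Draws i.i.d. bases at the supplied A, C, G, T probabilities from R's
#' seeded random number generator (one uniform draw per base, in sequence
#' order). Frequencies are renormalised if they sum to 1 within 1e-6.
#'
#' @param frequencies numeric(4), probabilities of A, C, G, T
#' @param length number of bases
#' @return a DNA string of `length` bases
#' @export
random_sequence <- function(frequencies, length) {
  frequencies <- check_frequencies(frequencies)
  length <- as.integer(length)
  if (length == 0L) return("")
  breaks <- cumsum(frequencies)[1:3]
  codes <- findInterval(stats::runif(length), breaks) + 1L
  codes_to_dna(codes)
}

# n x len integer code matrix; row j consumes the same RNG draws as the j-th
# of n successive random_sequence() calls
random_window_codes <- function(frequencies, n, len) {
  frequencies <- check_frequencies(frequencies)
  breaks <- cumsum(frequencies)[1:3]
  codes <- findInterval(stats::runif(n * len), breaks) + 1L
  matrix(codes, nrow = n, ncol = len, byrow = TRUE)
}

#' Base frequencies of the Xenopus tropicalis genome
#'
#' The nucleotide composition used by the published Monte-Carlo null:
#' A 0.299733, C 0.200318, G 0.200317, T 0.299632.
#' @return named numeric(4)
#' @export
xenopus_frequencies <- function() {
  c(A = 0.299733, C = 0.200318, G = 0.200317, T = 0.299632)
}

#' Monte-Carlo compositional null for APS/CPS occurrence
#'
#' Simulates `n_sequences` windows of `window_length` bases of i.i.d.
#' sequence at the given base composition, scans each with the APS/CPS
#' detector (same semantics as [scan_region()]), counts windows containing
#' at least one APS and at least one CPS, and scales the fractions to
#' `n_genes` gene-equivalents. This estimates how many TSS-upstream windows
#' would contain such elements by compositional chance alone; comparing
#' observed gene counts against it gives the enrichment ratio.
#'
#' Windows are generated from R's RNG seeded with `seed`, so results are
#' exactly reproducible; the per-window scan runs in compiled code but
#' counts identically to the R pipeline.
#'
#' @param config a [scan_config()]; its `motifs`, `apelen` and `motifgap`
#'   are used (all motifs jointly, with reverse complements)
#' @param table an [ape_table()]
#' @param frequencies numeric(4), A/C/G/T probabilities
#' @param n_sequences number of simulated windows
#' @param window_length window size in bp (typically `config$genegap`)
#' @param n_genes gene count the expectations are scaled to
#' @param seed integer RNG seed (recorded in the result)
#' @param observed_aps_genes,observed_cps_genes optional observed numbers of
#'   genes with >= 1 APS / CPS upstream, for enrichment ratios
#' @param batch_size windows simulated per batch (memory/time trade-off)
#' @return an object of class `null_result`: list with fields
#'   `n_sequences`, `window_length`, `frequencies`, `windows_with_aps`,
#'   `windows_with_cps`, `expected_aps_genes`, `expected_cps_genes`,
#'   `enrichment_aps`, `enrichment_cps`, `n_genes`, `seed`
#' @export
run_null <- function(config = scan_config(), table = default_ape_table(),
                     frequencies = xenopus_frequencies(),
                     n_sequences = 1e6, window_length = 500L,
                     n_genes = 18442L, seed = 1L,
                     observed_aps_genes = NULL, observed_cps_genes = NULL,
                     batch_size = 20000L) {
  stopifnot(inherits(config, "scan_config"), inherits(table, "ape_table"))
  frequencies <- check_frequencies(frequencies)
  n_sequences <- as.double(n_sequences)
  if (is.na(n_sequences) || n_sequences < 0) stop("`n_sequences` must be >= 0")
  window_length <- as.integer(window_length)
  motif_codes <- motif_code_patterns(config$motifs)
  set.seed(as.integer(seed))
  n_aps <- 0L
  n_cps <- 0L
  remaining <- n_sequences
  while (remaining > 0) {
    nb <- as.integer(min(remaining, batch_size))
    codes <- random_window_codes(frequencies, nb, window_length)
    hits <- scan_windows_cpp(codes, table$pair_values, config$apelen,
                             motif_codes, config$motifgap)
    n_aps <- n_aps + sum(hits[, 1])
    n_cps <- n_cps + sum(hits[, 2])
    remaining <- remaining - nb
  }
  frac_aps <- if (n_sequences > 0) n_aps / n_sequences else 0
  frac_cps <- if (n_sequences > 0) n_cps / n_sequences else 0
  structure(list(
    n_sequences = n_sequences,
    window_length = window_length,
    frequencies = frequencies,
    windows_with_aps = n_aps,
    windows_with_cps = n_cps,
    n_genes = as.integer(n_genes),
    expected_aps_genes = frac_aps * n_genes,
    expected_cps_genes = frac_cps * n_genes,
    enrichment_aps = if (is.null(observed_aps_genes)) NA_real_ else
      observed_aps_genes / (frac_aps * n_genes),
    enrichment_cps = if (is.null(observed_cps_genes)) NA_real_ else
      observed_cps_genes / (frac_cps * n_genes),
    observed_aps_genes = observed_aps_genes %||% NA_real_,
    observed_cps_genes = observed_cps_genes %||% NA_real_,
    motifs = config$motifs, apelen = config$apelen,
    motifgap = config$motifgap,
    seed = as.integer(seed)),
    class = "null_result")
}

# motifs + reverse complements as integer code vectors, deduplicated
motif_code_patterns <- function(motifs) {
  pats <- unique(c(toupper(motifs), revcomp(motifs)))
  lapply(pats, dna_codes)
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo null: %g windows of %d bp (seed %d)\n",
              x$n_sequences, x$window_length, x$seed))
  cat(sprintf("  windows with APS: %d  -> expected %.3f gene-equivalents\n",
              x$windows_with_aps, x$expected_aps_genes))
  cat(sprintf("  windows with CPS: %d  -> expected %.3f gene-equivalents\n",
              x$windows_with_cps, x$expected_cps_genes))
  if (!is.na(x$enrichment_aps)) {
    cat(sprintf("  APS enrichment (observed/expected): %.1f\n", x$enrichment_aps))
  }
  if (!is.na(x$enrichment_cps)) {
    cat(sprintf("  CPS enrichment (observed/expected): %.1f\n", x$enrichment_cps))
  }
  invisible(x)
}
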