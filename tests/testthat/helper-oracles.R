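# Independent brute-force oracles. These deliberately avoid the package's
# scanning code paths: direct lookups, interval enumeration and sliding-window
# string comparison only.

# string reversal + complement without using apescan::revcomp
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  cc <- unname(comp[ch])
  cc[is.na(cc)] <- "N"
  paste(rev(cc), collapse = "")
}

# per-position APE by direct two-lookup on the raw single-strand values
oracle_profile <- function(table, sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  vals <- rep(NA_real_, L)
  if (L >= 3) {
    for (i in 2:(L - 1)) {
      trip <- substr(sequence, i - 1, i + 1)
      if (grepl("[^ACGT]", trip)) next
      vals[i] <- unname(table$values[trip] + table$values[oracle_revcomp(trip)])
    }
  }
  vals
}

# every candidate interval, predicate tested directly (vectorised enumeration)
oracle_find_aps <- function(values, determined, apelen) {
  neg <- determined & !is.na(values) & values < 0
  L <- length(neg)
  empty <- data.frame(run_start = integer(0), run_end = integer(0))
  if (L == 0) return(empty)
  ij <- expand.grid(i = seq_len(L), j = seq_len(L))
  ij <- ij[ij$j >= ij$i & (ij$j - ij$i + 1) >= apelen, , drop = FALSE]
  if (!nrow(ij)) return(empty)
  cs0 <- c(0, cumsum(neg))
  all_neg <- (cs0[ij$j + 1] - cs0[ij$i]) == (ij$j - ij$i + 1)
  left_max <- ij$i == 1 | !neg[pmax(ij$i - 1, 1)]
  right_max <- ij$j == L | !neg[pmin(ij$j + 1, L)]
  keep <- all_neg & left_max & right_max
  ij <- ij[keep, , drop = FALSE]
  ij <- ij[order(ij$i), , drop = FALSE]
  data.frame(run_start = ij$i - 1L, run_end = ij$j - 1L)
}

# sliding-window comparison against motif and its reverse complement
oracle_find_motifs <- function(sequence, motifs) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  rows <- list()
  for (m in unique(toupper(motifs))) {
    rc <- oracle_revcomp(m)
    pats <- if (rc == m) c(forward = m) else c(forward = m, reverse_complement = rc)
    for (orient in names(pats)) {
      pat <- pats[[orient]]
      k <- nchar(pat)
      s <- 1
      while (s + k - 1 <= L) {
        if (substr(sequence, s, s + k - 1) == pat) {
          rows[[length(rows) + 1]] <- data.frame(
            start = s - 1L, end = s + k - 2L, matched_text = pat,
            orientation = orient, source_motif = m)
        }
        s <- s + 1
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      matched_text = character(0), orientation = character(0),
                      source_motif = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$orientation, out$source_motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all (APS, motif) pairs, predicate tested directly
oracle_find_cps <- function(aps, motifs, motifgap) {
  rows <- list()
  for (a in seq_len(nrow(aps))) {
    for (m in seq_len(nrow(motifs))) {
      gap <- motifs$start[m] - aps$span_end[a] - 1L
      if (motifs$start[m] > aps$span_end[a] && gap <= motifgap) {
        rows[[length(rows) + 1]] <- data.frame(
          aps_index = a, motif_index = m, gap = gap,
          cps_start = aps$span_start[a], cps_end = motifs$end[m])
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(aps_index = integer(0), motif_index = integer(0),
                      gap = integer(0), cps_start = integer(0),
                      cps_end = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cps_start, motifs$start[out$motif_index],
                   motifs$orientation[out$motif_index],
                   motifs$source_motif[out$motif_index]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
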