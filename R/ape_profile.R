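#' Per-base double-strand APE profile of a sequence
#'
#' Scores every position of a DNA sequence with the double-strand A-DNA
#' propensity energy of the trinucleotide centred there: the table value for
#' the forward-strand triplet plus the value for its reverse complement.
#' Position `i` therefore depends on bases `i-1`, `i`, `i+1`; the first and
#' last positions of the sequence have no complete triplet and are always
#' undetermined, as is any position whose window contains a non-ACGT base or
#' an undetermined triplet on either strand. Undetermined positions never
#' contribute a value (they are `NA`, not 0), and they break APS runs.
#'
#' Because the score sums both strands, the profile is strand-symmetric: the
#' profile of the reverse complement of `sequence` is the reversal of the
#' profile of `sequence`.
#'
#' @param table an [ape_table()]
#' @param sequence a DNA string (any case; normalised to uppercase)
#' @return an object of class `ape_profile`: a list with `sequence`
#'   (uppercased input), `values` (numeric, kcal/mol, `NA` where
#'   undetermined) and `determined` (logical), all of the sequence's length
#' @seealso [find_aps()], [pair_ape()]
#' @export
#' @examples
#' tab <- make_test_ape_table("uniform_negative")
#' ape_profile(tab, "ACGTA")$values  # NA -2 -2 -2 NA
ape_profile <- function(table, sequence) {
  stopifnot(inherits(table, "ape_table"), is.character(sequence),
            length(sequence) == 1L)
  sequence <- toupper(sequence)
  codes <- dna_codes(sequence)
  idx <- triplet_index(codes)
  values <- rep(NA_real_, length(codes))
  ok <- !is.na(idx)
  values[ok] <- table$pair_values[idx[ok]]
  structure(
    list(sequence = sequence,
         values = values,
         determined = !is.na(values)),
    class = "ape_profile")
}

#' @export
print.ape_profile <- function(x, ...) {
  cat(sprintf("APE profile over %d bp: %d determined positions, %d negative\n",
              length(x$values), sum(x$determined),
              sum(x$determined & x$values < 0)))
  invisible(x)
}
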