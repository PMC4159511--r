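DNA_BASES <- c("A", "C", "G", "T")

#' All 64 DNA trinucleotides in lexicographic order
#' @return character(64) of trinucleotides, `AAA` through `TTT`
#' @export
all_triplets <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Reverse complement of a DNA string
#'
#' Vectorised over `x`. Ambiguity codes are complemented per IUPAC where
#' defined; characters without a complement map to `N`.
#'
#' @param x character vector of DNA strings (any case; returned uppercase)
#' @return character vector of reverse complements
#' @export
#' @examples
#' revcomp("CCAAT")  # "ATTGG"
revcomp <- function(x) {
  x <- toupper(x)
  flipped <- chartr("ACGTRYKMBDHVN", "TGCAYRMKVHDBN", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Integer codes A=1 C=2 G=3 T=4; anything else NA.
dna_codes <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- match(ch, DNA_BASES)
  m
}

codes_to_dna <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

# 1..64 index of each complete ACGT triplet centred at interior positions;
# NA where the window is incomplete or contains a non-ACGT base.
triplet_index <- function(codes) {
  L <- length(codes)
  if (L < 3L) return(rep(NA_integer_, L))
  idx <- rep(NA_integer_, L)
  i <- 2:(L - 1L)
  idx[i] <- (codes[i - 1L] - 1L) * 16L + (codes[i] - 1L) * 4L + codes[i + 1L]
  idx
}

# index of the reverse complement triplet for each of the 64 triplet indices
revcomp_triplet_perm <- function() {
  trips <- all_triplets()
  match(revcomp(trips), trips)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
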