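# in-code fixture builders shared across test files

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# a fully random APE table: values in [-2, 2], n_undet undetermined triplets
random_ape_table <- function(n_undet = 14) {
  trips <- apescan::all_triplets()
  vals <- stats::runif(64, -2, 2)
  if (n_undet > 0) vals[sample.int(64, n_undet)] <- NA_real_
  names(vals) <- trips
  apescan::ape_table(vals, source_name = "random test table")
}

# a synthetic ape_profile with arbitrary sign/determinacy pattern
fake_profile <- function(values, determined = !is.na(values)) {
  values[!determined] <- NA_real_
  determined[c(1, length(determined))] <- FALSE
  values[!determined] <- NA_real_
  structure(list(sequence = strrep("N", length(values)), values = values,
                 determined = determined),
            class = "ape_profile")
}

write_tmp_gff3 <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}
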