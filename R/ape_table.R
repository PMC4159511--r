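#' Trinucleotide A-DNA propensity energy (APE) tables
#'
#' An `ape_table` stores single-strand A-DNA propensity energies (kcal/mol)
#' for DNA trinucleotides. Negative values indicate a propensity of the
#' triplet's central base step to adopt the A-form helix. Triplets without a
#' value are *undetermined*: positions whose score depends on them carry no
#' APE value and break runs during APS detection, rather than contributing 0.
#'
#' The per-base, double-strand APE used for scanning is not stored: it is the
#' sum of the table value for the triplet centred on a base and the value for
#' that triplet's reverse complement (the same triplet read on the other
#' strand in its own 5'->3' direction); see [pair_ape()].
#'
#' @param values named numeric vector; names are trinucleotides over ACGT,
#'   values are energies in kcal/mol, `NA` meaning undetermined. Triplets
#'   absent from `values` are undetermined.
#' @param source_name free-text provenance label for the table
#' @return an object of class `ape_table` with elements `values` (numeric(64),
#'   names all 64 triplets, `NA` = undetermined), `pair_values` (numeric(64),
#'   precomputed double-strand sums), and `source_name`.
#' @seealso [load_ape_table()], [default_ape_table()], [pair_ape()]
#' @export
ape_table <- function(values, source_name = "user") {
  trips <- all_triplets()
  if (is.null(names(values)) && length(values)) {
    stop("`values` must be a named numeric vector (names = triplets)")
  }
  nm <- toupper(names(values))
  bad <- nm[nchar(nm) != 3L | grepl("[^ACGT]", nm)]
  if (length(bad)) {
    stop("invalid triplet name(s): ", paste(unique(bad), collapse = ", "))
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    conflicting <- vapply(dup, function(t) {
      v <- values[nm == t]
      length(unique(v[!is.na(v)])) > 1L || anyNA(v) && any(!is.na(v))
    }, logical(1))
    if (any(conflicting)) {
      stop("duplicate triplet with conflicting value: ",
           paste(dup[conflicting], collapse = ", "))
    }
  }
  full <- rep(NA_real_, 64L)
  names(full) <- trips
  full[nm] <- as.numeric(values)
  rc <- revcomp_triplet_perm()
  obj <- structure(
    list(values = full,
         pair_values = full + full[rc],
         source_name = as.character(source_name)),
    class = "ape_table")
  obj
}

#' @export
print.ape_table <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("APE triplet table '%s': %d determined, %d undetermined\n",
              x$source_name, nd, 64L - nd))
  invisible(x)
}

#' Count of determined / undetermined triplets in a table
#' @param table an [ape_table()]
#' @return named integer vector with elements `determined` and `undetermined`
#' @export
ape_table_counts <- function(table) {
  stopifnot(inherits(table, "ape_table"))
  nd <- sum(!is.na(table$values))
  c(determined = nd, undetermined = 64L - nd)
}

#' Load an APE triplet table from a TSV file
#'
#' The file format is two tab-separated columns: a trinucleotide over ACGT and
#' either a decimal energy in kcal/mol or the literal `X` for an undetermined
#' triplet. Lines starting with `#` are comments. Triplets absent from the
#' file are undetermined.
#'
#' @param path path to the TSV file
#' @param source_name provenance label; defaults to the file name
#' @param quiet suppress the determined/undetermined count message
#' @return an [ape_table()]
#' @export
load_ape_table <- function(path, source_name = basename(path), quiet = FALSE) {
  if (!file.exists(path)) stop("APE table file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  vals <- numeric(0)
  nms <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 2L) {
      stop(sprintf("line %d of %s: expected 2 tab-separated fields, got %d",
                   i, path, length(fields)))
    }
    trip <- toupper(fields[1])
    if (nchar(trip) != 3L || grepl("[^ACGT]", trip)) {
      stop(sprintf("line %d of %s: malformed triplet '%s'", i, path, fields[1]))
    }
    if (toupper(fields[2]) == "X") {
      v <- NA_real_
    } else {
      v <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(v)) {
        stop(sprintf("line %d of %s: value '%s' is neither numeric nor 'X'",
                     i, path, fields[2]))
      }
    }
    if (trip %in% nms) {
      prev <- vals[match(trip, nms)]
      if (!identical(is.na(prev), is.na(v)) ||
          (!is.na(prev) && prev != v)) {
        stop(sprintf("line %d of %s: duplicate triplet '%s' with conflicting value",
                     i, path, trip))
      }
      next
    }
    nms <- c(nms, trip)
    vals <- c(vals, v)
  }
  names(vals) <- nms
  tab <- ape_table(vals, source_name = source_name)
  if (!quiet) {
    cts <- ape_table_counts(tab)
    message(sprintf("APE table '%s': %d determined, %d undetermined triplets",
                    source_name, cts["determined"], cts["undetermined"]))
  }
  tab
}

#' The packaged default APE table
#'
#' Loads the trinucleotide table shipped with the package
#' (`extdata/ape_triplet_table_synthetic.tsv`). The shipped table is a
#' synthetic reconstruction: the published single-strand energies are not
#' redistributed, so the packaged values reproduce the qualitative sign
#' structure of A-philicity (G/C blocks negative, T-substituted C-block
#' starts negative, repeated ATGC blocks weakly negative, A/T-rich positive)
#' with 14 undetermined triplets, at plausible magnitudes. The scanning
#' engine is value-agnostic: any table in the documented TSV dialect can be
#' substituted via [load_ape_table()].
#'
#' @return an [ape_table()] with 50 determined and 14 undetermined triplets
#' @export
default_ape_table <- function() {
  path <- system.file("extdata", "ape_triplet_table_synthetic.tsv",
                      package = "apescan", mustWork = TRUE)
  load_ape_table(path, source_name = "synthetic reconstruction", quiet = TRUE)
}

#' Double-strand APE value of a trinucleotide
#'
#' The APE contribution of the base centred in `triplet` is the sum of the
#' single-strand table values for the triplet on the forward strand and for
#' its reverse complement (the same positions read on the reverse strand).
#' The result is undetermined (`NA`) if either lookup is undetermined or the
#' triplet contains a non-ACGT character.
#'
#' @param table an [ape_table()]
#' @param triplet a 3-letter DNA string (case-insensitive)
#' @return energy in kcal/mol, or `NA` if undetermined
#' @export
#' @examples
#' tab <- make_test_ape_table("uniform_negative")
#' pair_ape(tab, "ACG")  # -2
pair_ape <- function(table, triplet) {
  stopifnot(inherits(table, "ape_table"))
  triplet <- toupper(triplet)
  if (nchar(triplet) != 3L || grepl("[^ACGT]", triplet)) return(NA_real_)
  unname(table$pair_values[triplet])
}
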