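# shared fixture: a deterministic planted scan with genes on both strands
trackio_fixture <- function(seed = 23, n_genes = 4) {
  spec <- plant_spec(n_genes = n_genes, directives = c("cps", "aps_only"),
                     seed = seed)
  fix <- make_synthetic_genome(spec)
  scan <- scan_genes(fix$genome, fix$genes, make_test_ape_table("gc_negative"),
                     scan_config())
  list(fix = fix, scan = scan)
}

test_that("the results TSV has a stable header and deterministic order", {
  tf <- trackio_fixture()
  path <- tempfile(fileext = ".tsv")
  write_results_tsv(tf$scan, path)
  lines <- readLines(path)
  expect_equal(lines[1], paste(
    c("gene_id", "gene_name", "seqid", "strand", "tss", "aps_start",
      "aps_end", "run_length", "motif_start", "motif_end", "matched_text",
      "orientation", "gap", "cps_start", "cps_end"), collapse = "\t"))
  expect_equal(length(lines), nrow(tf$scan$results) + 1L)

  # empty scan: header only
  p2 <- tempfile(fileext = ".tsv")
  write_results_tsv(tf$scan$results[0, ], p2)
  expect_equal(length(readLines(p2)), 1L)

  # re-read and compare coordinates against the truth table
  got <- utils::read.delim(path)
  truth <- tf$fix$truth[tf$fix$truth$directive == "cps", ]
  expect_equal(sort(got$cps_start), sort(truth$genomic_cps_start))
  expect_equal(sort(got$cps_end), sort(truth$genomic_cps_end))
  expect_equal(nrow(got), nrow(truth))
})

test_that("BED tracks use 0-based half-open coordinates and round-trip", {
  tf <- trackio_fixture()
  prefix <- tempfile()
  paths <- write_bed(tf$scan, prefix)
  expect_true(all(file.exists(paths)))

  # independent parser: rtracklayer converts BED back to 1-based inclusive
  aps_back <- rtracklayer::import(paths["aps"], format = "bed")
  a <- tf$scan$aps
  expect_equal(BiocGenerics::start(aps_back), a$genomic_span_start[
    order(a$seqid, a$genomic_span_start, a$gene_id)])
  expect_equal(BiocGenerics::end(aps_back), a$genomic_span_end[
    order(a$seqid, a$genomic_span_start, a$gene_id)])

  motif_back <- rtracklayer::import(paths["motif"], format = "bed")
  m <- tf$scan$motifs[order(tf$scan$motifs$seqid, tf$scan$motifs$genomic_start,
                            tf$scan$motifs$gene_id,
                            tf$scan$motifs$source_motif), ]
  expect_equal(BiocGenerics::start(motif_back), m$genomic_start)
  expect_equal(BiocGenerics::end(motif_back), m$genomic_end)

  # raw-line convention check: 1-based inclusive [s, e] -> "s-1  e"
  line2 <- strsplit(readLines(paths["aps"])[2], "\t")[[1]]
  expect_equal(as.integer(line2[2]),
               min(a$genomic_span_start) - 1L)
})

test_that("APE sign segments tile each search region without gaps", {
  tf <- trackio_fixture()
  prefix <- tempfile()
  paths <- write_bed(tf$scan, prefix)
  seg <- rtracklayer::import(paths["apesign"], format = "bed")
  labels <- sub("^g[0-9]+_", "", seg$name)
  expect_true(all(labels %in% c("neg", "pos", "undet")))
  for (gid in names(tf$scan$gene_scans)) {
    region <- tf$scan$gene_scans[[gid]]$region
    mine <- seg[grepl(paste0("^", gid, "_"), seg$name)]
    mine <- mine[order(BiocGenerics::start(mine))]
    # tiles: first starts at region start, last ends at region end, adjacent
    expect_equal(BiocGenerics::start(mine)[1], region$genomic_start)
    expect_equal(max(BiocGenerics::end(mine)), region$genomic_end)
    if (length(mine) > 1) {
      expect_equal(BiocGenerics::start(mine)[-1],
                   BiocGenerics::end(mine)[-length(mine)] + 1L)
    }
    # adjacent segments never share a label (maximality of the segmentation)
    lab <- sub("^g[0-9]+_", "", mine$name)
    if (length(lab) > 1) expect_true(all(lab[-1] != lab[-length(lab)]))
  }
})

test_that("WIG fixedStep blocks reproduce the determined APE values", {
  tf <- trackio_fixture()
  path <- tempfile(fileext = ".wig")
  write_wig(tf$scan, path)
  wig <- rtracklayer::import(path, format = "wig")
  wig <- wig[order(BiocGenerics::start(wig))]
  # reconstruct expected per-genomic-position values from the profiles
  exp_pos <- integer(0); exp_val <- numeric(0)
  for (gid in names(tf$scan$gene_scans)) {
    gs <- tf$scan$gene_scans[[gid]]
    prof <- gs$scan$profile
    vals <- prof$values; det <- prof$determined
    if (gs$region$strand == "-") { vals <- rev(vals); det <- rev(det) }
    gpos <- gs$region$genomic_start:gs$region$genomic_end
    exp_pos <- c(exp_pos, gpos[det])
    exp_val <- c(exp_val, vals[det])
  }
  o <- order(exp_pos)
  expect_equal(BiocGenerics::start(wig), exp_pos[o])
  expect_equal(wig$score, exp_val[o])
  # undetermined positions are absent entirely
  expect_false(any(BiocGenerics::start(wig) %in% setdiff(
    tf$scan$gene_scans[[1]]$region$genomic_start:
      tf$scan$gene_scans[[1]]$region$genomic_end, exp_pos)))
})

test_that("GFF3 output links CPS/APS/motif features and round-trips", {
  tf <- trackio_fixture()
  path <- tempfile(fileext = ".gff3")
  write_gff(tf$scan, path)
  gr <- rtracklayer::import(path, format = "gff3")
  res <- tf$scan$results
  expect_equal(sum(gr$type == "CPS"), nrow(res))
  expect_equal(sum(gr$type == "APS"), nrow(res))
  expect_equal(sum(gr$type == "motif"), nrow(res))
  cps <- gr[gr$type == "CPS"]
  cps <- cps[order(BiocGenerics::start(cps))]
  expect_equal(BiocGenerics::start(cps), sort(res$cps_start))
  # children reference their CPS parent
  aps <- gr[gr$type == "APS"]
  expect_true(all(lengths(aps$Parent) == 1L))
  expect_true(all(unlist(aps$Parent) %in% cps$ID))
  # convention law vs BED: GFF start == BED start + 1, GFF end == BED end.
  # The BED APS track carries every APS (including APS-only genes); the GFF
  # carries the CPS-linked ones, so compare on the GFF's spans.
  prefix <- tempfile()
  paths <- write_bed(tf$scan, prefix)
  bed_aps <- read.table(paths["aps"], skip = 1, sep = "\t")
  gff_aps <- gr[gr$type == "APS"]
  expect_equal(sort(BiocGenerics::start(gff_aps)), sort(res$aps_start))
  key_bed <- paste(bed_aps$V2 + 1L, bed_aps$V3)
  key_gff <- paste(BiocGenerics::start(gff_aps), BiocGenerics::end(gff_aps))
  expect_true(all(key_gff %in% key_bed))

  # empty results: version pragma only
  p0 <- tempfile(fileext = ".gff3")
  write_gff(tf$scan$results[0, ], p0)
  expect_equal(readLines(p0), "##gff-version 3")
})

test_that("all writers are byte-deterministic", {
  tf <- trackio_fixture()
  t1 <- tempfile(); t2 <- tempfile()
  write_results_tsv(tf$scan, t1); write_results_tsv(tf$scan, t2)
  expect_identical(readLines(t1), readLines(t2))
  write_wig(tf$scan, t1); write_wig(tf$scan, t2)
  expect_identical(readLines(t1), readLines(t2))
  write_gff(tf$scan, t1); write_gff(tf$scan, t2)
  expect_identical(readLines(t1), readLines(t2))
  p1 <- write_bed(tf$scan, tempfile()); p2 <- write_bed(tf$scan, tempfile())
  for (k in 1:3) expect_identical(readLines(p1[k]), readLines(p2[k]))
})
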