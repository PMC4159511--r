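test_that("find_aps reports maximal negative runs with flanking spans", {
  uni <- make_test_ape_table("uniform_negative")

  # all-positive profile: nothing
  p <- fake_profile(c(NA, 1, 2, 3, 1, NA))
  expect_equal(nrow(find_aps(p, 1)), 0L)

  # 14 A's, apelen 12: one run over the 12 interior positions, span 14
  p <- ape_profile(uni, strrep("A", 14))
  hits <- find_aps(p, 12)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$run_start, 1L)
  expect_equal(hits$run_end, 12L)
  expect_equal(hits$run_length, 12L)
  expect_equal(hits$span_start, 0L)
  expect_equal(hits$span_end, 13L)
  expect_equal(hits$span_end - hits$span_start + 1L, 14L)
  expect_equal(hits$min_ape, -2)
  expect_equal(hits$sum_ape, -24)

  # zero breaks a run; undetermined breaks a run
  p <- fake_profile(c(NA, -1, -1, 0, -1, -1, NA))
  expect_equal(find_aps(p, 2)$run_start, c(1L, 4L))
  p <- fake_profile(c(NA, -1, -1, NA, -1, -1, NA))
  expect_equal(find_aps(p, 2)$run_start, c(1L, 4L))

  expect_error(find_aps(p, 0), "apelen")
})

test_that("find_aps matches interval-enumeration brute force on random profiles", {
  set.seed(101)
  for (rep in 1:500) {
    L <- sample(0:120, 1)
    vals <- stats::rnorm(L)
    det <- stats::runif(L) < 0.8
    p <- fake_profile(vals, det)
    apelen <- sample(c(1L, 5L, 10L), 1)
    got <- find_aps(p, apelen)
    want <- oracle_find_aps(p$values, p$determined, apelen)
    expect_equal(got[c("run_start", "run_end")], want)
    if (nrow(got)) {
      expect_equal(got$span_start, got$run_start - 1L)
      expect_equal(got$span_end, got$run_end + 1L)
      expect_true(all(got$run_length >= apelen))
    }
  }
})

test_that("find_motifs matches sliding-window brute force and handles orientation", {
  # reverse-complement hit is reported by its matched text
  hits <- find_motifs(paste0("AAAA", "CCGCCC", "AAAA"), "GGGCGG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$orientation, "reverse_complement")
  expect_equal(hits$matched_text, "CCGCCC")
  expect_equal(hits$start, 4L)

  # case-insensitive
  hits <- find_motifs("xxccaatxx", "CCAAT")
  expect_equal(hits$start, 2L)
  expect_equal(hits$orientation, "forward")

  # palindromic motif reported once per position, forward
  hits <- find_motifs("AAGATCAA", "GATC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$orientation, "forward")

  # overlapping occurrences are all reported
  hits <- find_motifs("AAAAA", "AAA")
  expect_equal(hits$start[hits$orientation == "forward"], c(0L, 1L, 2L))

  set.seed(202)
  for (rep in 1:500) {
    s <- random_dna(sample(0:80, 1))
    m <- random_dna(sample(4:6, 1))
    got <- find_motifs(s, m)
    want <- oracle_find_motifs(s, m)
    expect_equal(got, want)
  }
})

test_that("find_cps pairs APS and motifs exactly within the gap bound", {
  aps <- data.frame(run_start = 1L, run_end = 12L, span_start = 0L,
                    span_end = 13L, run_length = 12L, min_ape = -2,
                    sum_ape = -24)
  mot <- data.frame(start = 14L, end = 18L, matched_text = "CCAAT",
                    orientation = "forward", source_motif = "CCAAT")
  cps <- find_cps(aps, mot, 20)
  expect_equal(nrow(cps), 1L)
  expect_equal(cps$gap, 0L)
  expect_equal(cps$cps_start, 0L)
  expect_equal(cps$cps_end, 18L)

  # gap 21 > motifgap 20: excluded; gap exactly 20: included
  mot$start <- 35L; mot$end <- 39L
  expect_equal(nrow(find_cps(aps, mot, 20)), 0L)
  mot$start <- 34L; mot$end <- 38L
  expect_equal(find_cps(aps, mot, 20)$gap, 20L)

  # motif overlapping or preceding the span never pairs
  mot$start <- 13L; mot$end <- 17L
  expect_equal(nrow(find_cps(aps, mot, 20)), 0L)

  set.seed(303)
  for (rep in 1:200) {
    n_aps <- sample(0:4, 1); n_mot <- sample(0:6, 1)
    rs <- sort(sample(1:180, n_aps))
    aps <- data.frame(run_start = rs, run_end = rs + 10L,
                      span_start = rs - 1L, span_end = rs + 11L,
                      run_length = rep(11L, n_aps), min_ape = rep(-1, n_aps),
                      sum_ape = rep(-11, n_aps))
    ms <- sort(sample(0:195, n_mot))
    mot <- data.frame(start = ms, end = ms + 4L,
                      matched_text = rep("CCAAT", n_mot),
                      orientation = rep("forward", n_mot),
                      source_motif = rep("CCAAT", n_mot))
    gapmax <- sample(0:30, 1)
    got <- find_cps(aps, mot, gapmax)
    want <- oracle_find_cps(aps, mot, gapmax)
    expect_equal(got[c("aps_index", "motif_index", "gap", "cps_start", "cps_end")],
                 want)
  }
})

test_that("scan_region composes the stages and finds planted elements", {
  tab <- make_test_ape_table("uniform_negative")
  empty <- scan_region("", tab, scan_config())
  expect_equal(nrow(empty$cps), 0L)
  expect_equal(nrow(empty$aps), 0L)
  expect_equal(nrow(empty$motifs), 0L)

  # planted G-run + gap + CCAAT; the gc_negative table scores exactly the
  # G/C-centred positions negative, so the planted run is the only APS
  set.seed(404)
  s <- paste0(random_dna(30, bases = c("A", "T")), strrep("G", 12), "ATTAT",
              "CCAAT", random_dna(48, bases = c("A", "T")))
  rs <- scan_region(s, make_test_ape_table("gc_negative"), scan_config())
  expect_gte(nrow(rs$cps), 1L)
  expect_true(any(rs$cps$matched_text == "CCAAT" & rs$cps$motif_start == 47))
})

test_that("scan_region equals the composed brute-force oracles end-to-end", {
  set.seed(505)
  cfg_motifs <- c("CCAAT", "GGGCGG")
  for (rep in 1:200) {
    tab <- random_ape_table(n_undet = sample(0:20, 1))
    s <- random_dna(500)
    apelen <- sample(c(2L, 3L, 10L), 1)
    gapmax <- sample(c(0L, 5L, 20L), 1)
    rs <- scan_region(s, tab, scan_config(motifs = cfg_motifs, apelen = apelen,
                                          motifgap = gapmax))
    prof <- oracle_profile(tab, s)
    aps_o <- oracle_find_aps(prof, !is.na(prof), apelen)
    expect_equal(rs$aps[c("run_start", "run_end")], aps_o)
    mot_o <- oracle_find_motifs(s, cfg_motifs)
    expect_equal(rs$motifs, mot_o)
    aps_full <- cbind(aps_o, span_start = aps_o$run_start - 1L,
                      span_end = aps_o$run_end + 1L)
    cps_o <- oracle_find_cps(aps_full, mot_o, gapmax)
    expect_equal(rs$cps[c("aps_index", "motif_index", "gap", "cps_start",
                          "cps_end")], cps_o)
  }
})

test_that("APS sets shrink with apelen and CPS sets grow with motifgap", {
  set.seed(606)
  tab <- random_ape_table()
  for (rep in 1:20) {
    s <- random_dna(400)
    p <- ape_profile(tab, s)
    prev <- NULL
    for (k in 1:8) {
      runs <- find_aps(p, k)
      if (!is.null(prev)) {
        # every run at apelen k is among the runs at apelen k-1
        key <- paste(runs$run_start, runs$run_end)
        expect_true(all(key %in% paste(prev$run_start, prev$run_end)))
        expect_lte(nrow(runs), nrow(prev))
      }
      prev <- runs
    }
    mot <- find_motifs(s, c("CCAAT", "AGATA"))
    aps <- find_aps(p, 3)
    prev_cps <- NULL
    for (g in c(0, 2, 5, 10, 20)) {
      cps <- find_cps(aps, mot, g)
      if (!is.null(prev_cps)) {
        key <- paste(cps$aps_index, cps$motif_index)
        expect_true(all(paste(prev_cps$aps_index, prev_cps$motif_index) %in% key))
      }
      expect_lte(nrow(cps), nrow(aps) * nrow(mot))
      prev_cps <- cps
    }
  }
})

test_that("scanning is deterministic for identical inputs", {
  set.seed(707)
  tab <- random_ape_table()
  s <- random_dna(300)
  cfg <- scan_config(motifs = c("CCAAT", "GGGCGG"), apelen = 3)
  r1 <- scan_region(s, tab, cfg)
  r2 <- scan_region(s, tab, cfg)
  expect_identical(r1$cps, r2$cps)
  expect_identical(r1$aps, r2$aps)
  expect_identical(r1$motifs, r2$motifs)
})

test_that("scan_config validates its parameters", {
  expect_error(scan_config(apelen = 0), "apelen")
  expect_error(scan_config(motifgap = -1), "motifgap")
  expect_error(scan_config(genegap = 0), "genegap")
  expect_error(scan_config(motifs = "CCNAT"), "ACGT")
  expect_error(scan_config(motifs = character(0)), "motif")
  cfg <- scan_config()
  expect_equal(cfg$motifs, "CCAAT")
  expect_equal(cfg$apelen, 10L)
  expect_equal(cfg$motifgap, 20L)
  expect_equal(cfg$genegap, 500L)
})
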