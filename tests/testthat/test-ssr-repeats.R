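test_that("pure repeats and homopolymers are reported exactly", {
  h <- scan_ssrs("ACACACAC", min_repeats = c(8, 3))
  expect_equal(h, data.frame(motif = "AC", repeat_count = 4L,
                             start = 1L, end = 8L,
                             stringsAsFactors = FALSE))

  h1 <- scan_ssrs("GGGGG", min_repeats = c(5, 5))
  expect_equal(h1$motif, "G")
  expect_equal(h1$repeat_count, 5L)
  expect_equal(c(h1$start, h1$end), c(1L, 5L))

  # below threshold: nothing
  expect_equal(nrow(scan_ssrs("ACACAC", min_repeats = c(8, 4))), 0L)
  # invariant: hit width equals unit times count
  expect_equal(h$end - h$start + 1L, nchar(h$motif) * h$repeat_count)
})

test_that("gaps, N and invalid symbols are handled", {
  expect_error(scan_ssrs("ACGTX"), "invalid")
  # N interrupts a run
  h <- scan_ssrs("AAAANAAAA", min_repeats = c(4, 5))
  expect_equal(h$repeat_count, c(4L, 4L))
  expect_equal(h$start, c(1L, 6L))
  # gap characters never join a hit
  expect_equal(nrow(scan_ssrs("--------", min_repeats = c(2, 2))), 0L)
})

test_that("trailing partial copies are trimmed but block nothing", {
  # ACACA: two full AC copies plus a partial; run is maximal
  h <- scan_ssrs("TTGACACACACAGTT", min_repeats = c(8, 4))
  expect_equal(h$motif, "AC")
  expect_equal(h$repeat_count, 4L)
  expect_equal(c(h$start, h$end), c(4L, 11L))
})

test_that("periodic motifs are reported at their shortest unit", {
  # a CT run must not also surface as CTCT 4-mers
  h <- scan_ssrs("CTCTCTCTCTCT", min_unit = 1, max_unit = 6,
                 min_repeats = c(8, 4, 4, 2, 4, 2))
  expect_equal(h$motif, "CT")
  expect_equal(h$repeat_count, 6L)
})

test_that("scanner matches the exhaustive oracle on planted sequences", {
  thresholds <- c(8L, 5L, 4L, 4L, 4L, 4L)
  plants <- list(list(motif = "CT", repeats = 10, position = 50),
                 list(motif = "T", repeats = 15, position = 120),
                 list(motif = "GAT", repeats = 6, position = 200))
  seqs <- generate_ssr_sequences(40, 500, planted = plants, seed = 77)
  for (s in as.character(seqs)) {
    got <- scan_ssrs(s, min_repeats = thresholds)
    want <- oracle_scan_ssrs(s, min_repeats = thresholds)
    expect_equal(got, want)
  }
  # every planted array is recovered exactly
  hits <- scan_ssrs_set(seqs, min_repeats = thresholds)
  for (p in plants) {
    sub <- hits[hits$motif == p$motif & hits$start == p$position, ]
    expect_equal(nrow(sub), length(seqs))
    expect_true(all(sub$repeat_count == p$repeats))
  }
})

test_that("hits mirror under reverse complement", {
  plants <- list(list(motif = "AG", repeats = 8, position = 40),
                 list(motif = "TTG", repeats = 5, position = 150))
  seqs <- generate_ssr_sequences(10, 300, planted = plants, seed = 5)
  for (s in as.character(seqs)) {
    fwd <- scan_ssrs(s)
    rev <- scan_ssrs(reverse_complement(s))
    L <- nchar(s)
    for (p in plants) {
      u <- nchar(p$motif)
      f <- fwd[fwd$start == p$position & nchar(fwd$motif) == u, ]
      expect_equal(nrow(f), 1L)
      mirrored <- rev[rev$start == L - f$end + 1L &
                        rev$end == L - f$start + 1L, ]
      expect_equal(nrow(mirrored), 1L)
      expect_equal(mirrored$repeat_count, f$repeat_count)
      # motif maps to a rotation class of the reverse complement
      expect_equal(oracle_rotation(mirrored$motif),
                   oracle_rotation(reverse_complement(f$motif)))
    }
  }
})

test_that("batch scanning is independent of batch composition", {
  seqs <- generate_ssr_sequences(
    6, 400, planted = list(list(motif = "CA", repeats = 7,
                                position = 100)), seed = 31)
  all_hits <- scan_ssrs_set(seqs)
  for (i in seq_along(seqs)) {
    solo <- scan_ssrs_set(seqs[i])
    sub <- all_hits[all_hits$seq_id == names(seqs)[i], ]
    rownames(sub) <- NULL
    expect_equal(sub, solo)
  }
})

test_that("consensus mismatches count columns differing from majority", {
  same <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT")
  cm <- consensus_mismatches(same)
  expect_equal(unname(c(cm)), c(0L, 0L, 0L))

  # one deviant sequence scores exactly its k altered columns
  dev <- c(same, d = "ACGAACGA")
  cm2 <- consensus_mismatches(dev)
  expect_equal(unname(c(cm2)), c(0L, 0L, 0L, 2L))

  expect_error(consensus_mismatches(c(a = "ACGT", b = "ACG")), "ragged")
  expect_error(consensus_mismatches(c(a = "ACGT")), "at least 2")
})

test_that("consensus mismatch counts match a columnwise oracle", {
  set.seed(8)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 4 * 200,
                         replace = TRUE,
                         prob = c(0.23, 0.23, 0.23, 0.23, 0.08)),
                  nrow = 4)
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- paste0("s", 1:4)
    got <- consensus_mismatches(seqs)

    # oracle: per column, majority base over ACGT; tie or no base ->
    # column skipped; a scored sequence mismatches when its symbol
    # (base, gap or N) differs from the consensus base
    want <- integer(4)
    scored <- 0L
    for (j in seq_len(ncol(mat))) {
      col <- mat[, j]
      tab <- table(col[col %in% c("A", "C", "G", "T")])
      if (!length(tab)) next
      winners <- names(tab)[tab == max(tab)]
      if (length(winners) != 1L) next
      scored <- scored + 1L
      want <- want + (col != winners)
    }
    expect_equal(unname(c(got)), want)
    expect_equal(attr(got, "columns_scored"), scored)
    # invariant: total equals the sum of per-column indicators
    expect_equal(sum(c(got)), sum(want))
  }
})

test_that("gap columns never form consensus but do score mismatches", {
  seqs <- c(a = "A-CC", b = "A-CC", c = "A--C", d = "T-CC")
  cm <- consensus_mismatches(seqs)
  # column 2 is all gaps: skipped; column 3 consensus C, c has a gap
  expect_equal(attr(cm, "columns_scored"), 3L)
  expect_equal(unname(c(cm)), c(0L, 0L, 1L, 1L))
  expect_equal(attr(cm, "consensus"), "A.CC")
})

test_that("band size checks are inclusive on both boundaries", {
  expect_true(band_size_check(150, 100, 200))
  expect_true(band_size_check(200, 100, 200))
  expect_true(band_size_check(100, 100, 200))
  expect_false(band_size_check(250, 100, 200))
  expect_error(band_size_check(150, 200, 100), "inverted")
  expect_error(band_size_check(-5, 100, 200), "positive")
})

test_that("GFF3 output carries 1-based inclusive coordinates", {
  seqs <- generate_ssr_sequences(
    2, 200, planted = list(list(motif = "AT", repeats = 6,
                                position = 20)), seed = 2)
  hits <- scan_ssrs_set(seqs)
  f <- tempfile(fileext = ".gff3")
  on.exit(unlink(f))
  write_ssr_gff3(hits, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(fields[4]), 20L)
  expect_equal(as.integer(fields[5]), 31L)
})
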