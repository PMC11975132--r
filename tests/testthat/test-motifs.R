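test_that("score matrices are min-max normalised with exact endpoints", {
  pfm <- matrix(c(10, 0, 0, 0), 4, 1,
                dimnames = list(c("A", "C", "G", "T")))
  sm <- pfmToScoreMatrix(pfm, "mono")
  expect_equal(unname(sm@weights["A", 1]), 1)
  expect_equal(unname(sm@weights["C", 1]), 0)

  sm2 <- pfmToScoreMatrix(consensusPFM("ACGTTG"), "hex")
  scores <- scanRegion("ACGTTG", sm2)
  expect_equal(max(scores$sp), 1)  # consensus window scores exactly 1
  expect_true(validObject(sm2))
})

test_that("degenerate and malformed matrices are rejected", {
  uni <- matrix(5, 4, 3, dimnames = list(c("A", "C", "G", "T")))
  expect_error(pfmToScoreMatrix(uni, "uniform"),
               class = "trnDegenerateMatrix")
  zero <- consensusPFM("ACG")
  zero[, 2] <- 0
  expect_error(pfmToScoreMatrix(zero), "all-zero column at position 2")
  expect_error(pfmToScoreMatrix(matrix(1, 4, 0)), "at least one")
})

test_that("scanning finds planted sites on both strands with exact scores", {
  sm <- pfmToScoreMatrix(consensusPFM("ACGTACCA"), "t")
  set.seed(21)
  seq <- randomSeq(60)
  seq <- paste0(seq, "ACGTACCA", randomSeq(40), "TGGTACGT",
                randomSeq(30))
  hits <- scanRegion(seq, sm)
  top2 <- hits[hits$sp > 0.999, ]
  expect_equal(sort(top2$offset), c(60, 108))
  expect_equal(top2$strand[top2$offset == 60], "+")
  expect_equal(top2$strand[top2$offset == 108], "-")
  # shorter than the motif: empty, not an error
  expect_equal(nrow(scanRegion("ACGT", sm)), 0L)
})

test_that("scanRegion agrees with an exhaustive naive scorer", {
  set.seed(22)
  for (rep in 1:12) {
    cons <- randomSeq(sample(6:10, 1))
    sm <- pfmToScoreMatrix(consensusPFM(cons, strong = sample(20:60, 1)),
                           "x")
    seq <- randomSeq(sample(80:300, 1))
    got <- scanRegion(seq, sm)
    want <- naiveTopSites(naiveScan(seq, sm), nchar(cons))
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$sp, want$sp, tolerance = 1e-12)
    # ordering invariant: scores descending, at most 4, non-overlapping
    expect_true(all(diff(got$sp) <= 1e-12))
    expect_lte(nrow(got), 4L)
    if (nrow(got) > 1L) {
      o <- sort(got$offset)
      expect_true(all(diff(o) >= nchar(cons)))
    }
  }
})

test_that("N bases score as the per-position minimum", {
  sm <- pfmToScoreMatrix(consensusPFM("AAAA"), "a4")
  sN <- scanRegion("AANA", sm, nSites = 1L)
  sC <- scanRegion("AACA", sm, nSites = 1L)
  expect_equal(sN$sp, sC$sp, tolerance = 1e-12)
})

test_that("repressor choice follows the competition criterion", {
  matrices <- list(
    ME = pfmToScoreMatrix(consensusPFM("ACGTACGT"), "ME"),
    R1 = pfmToScoreMatrix(consensusPFM("ACGTACGA"), "R1"),
    R2 = pfmToScoreMatrix(consensusPFM("ACGTACGA"), "R2"))
  seq <- paste0(strrep("G", 20), "ACGTACGT", strrep("G", 20))
  # equal scores and Ki: double concentration wins (criterion linear in R)
  sel <- selectRepressor("ME", seq, 20L, 8L, matrices,
                         c(ME = 1, R1 = 2, R2 = 1),
                         ki = c(R1 = 1, R2 = 1), a = 10, floor = 0)
  expect_equal(sel$repressor_id, "R1")
  # exact tie: lexicographically smallest id
  sel <- selectRepressor("ME", seq, 20L, 8L, matrices,
                         c(ME = 1, R1 = 1, R2 = 1),
                         ki = c(R1 = 1, R2 = 1), a = 10, floor = 0)
  expect_equal(sel$repressor_id, "R1")
  # larger Ki loses
  sel <- selectRepressor("ME", seq, 20L, 8L, matrices,
                         c(ME = 1, R1 = 1, R2 = 1),
                         ki = c(R1 = 100, R2 = 1), a = 10, floor = 0)
  expect_equal(sel$repressor_id, "R2")
  # floor above every criterion value: no repressor attached
  sel <- selectRepressor("ME", seq, 20L, 8L, matrices,
                         c(ME = 1, R1 = 1, R2 = 1),
                         ki = c(R1 = 1, R2 = 1), a = 10, floor = 1e6)
  expect_true(is.na(sel$repressor_id))
  # no candidates at all
  sel <- selectRepressor("ME", seq, 20L, 8L, matrices["ME"],
                         c(ME = 1), a = 10)
  expect_true(is.na(sel$repressor_id))
})

test_that("profile building matches the per-site repressor op", {
  # mixed motif widths exercise the rolling-window fast path against
  # the direct per-site implementation
  set.seed(23)
  matrices <- list(
    TFA = pfmToScoreMatrix(consensusPFM("ACGTACGTAC"), "TFA"),
    TFB = pfmToScoreMatrix(consensusPFM("TTGACC"), "TFB"),
    TFC = pfmToScoreMatrix(consensusPFM("GGATCCGGATCC"), "TFC"))
  seq <- randomSeq(300)
  seq <- paste0(substr(seq, 1, 50), "ACGTACGTAC",
                substr(seq, 61, 120), "TTGACC",
                substr(seq, 127, 300))
  conc <- c(TFA = 2, TFB = 1, TFC = 3)
  ki <- c(TFA = 1, TFB = 1, TFC = 1)
  params <- modelParams(a = 10, scoreFloor = 0.5)
  scan <- trnscreen:::.scanRegionSites(seq, matrices, params)
  df <- trnscreen:::.attachRepressors(scan, conc, ki, 10, repFloor = 0)
  for (i in seq_len(nrow(df))) {
    ref <- selectRepressor(df$tf_id[i], seq, df$offset[i],
                           nchar(c(TFA = "ACGTACGTAC", TFB = "TTGACC",
                                   TFC = "GGATCCGGATCC")[[df$tf_id[i]]]),
                           matrices, conc, ki, a = 10, floor = 0)
    expect_equal(df$repressor_id[i], ref$repressor_id)
    if (!is.na(ref$sq))
      expect_equal(df$sq[i], ref$sq, tolerance = 1e-12)
  }
})

test_that("JASPAR matrices round-trip through the text format", {
  pfms <- list(M1 = consensusPFM("ACGTAA"), M2 = consensusPFM("GGTACA"))
  path <- tempfile(fileext = ".jaspar")
  writeJasparMatrices(pfms, path)
  back <- readJasparMatrices(path)
  expect_named(back, c("M1", "M2"))
  expect_equal(back$M1@weights,
               pfmToScoreMatrix(pfms$M1, "M1")@weights)
  # degenerate block is dropped with a warning
  writeJasparMatrices(c(pfms, list(BAD = matrix(3, 4, 2,
    dimnames = list(c("A", "C", "G", "T"))))), path)
  expect_warning(back2 <- readJasparMatrices(path), "degenerate")
  expect_named(back2, c("M1", "M2"))
})

test_that("binding-site tables round-trip and profiles are deterministic", {
  fx <- smallFixture()
  sites <- promoterSites(fx$model)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeBindingSites(sites, p1)
  back <- readBindingSites(p1)
  ord <- order(sites$gene_id, sites$tf_id, sites$site_rank)
  expect_equal(back$sp, sites$sp[ord], tolerance = 1e-14)
  expect_equal(back$offset, sites$offset[ord])
  expect_equal(back$repressor_id, sites$repressor_id[ord])
  writeBindingSites(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("planted fixture sites are all recovered with score 1", {
  fx <- smallFixture()
  gt <- fx$groundTruth
  ps <- promoterSites(fx$model)
  gtp <- gt[gt$region == "promoter" & gt$gene_id %in% ps$gene_id, ]
  found <- mapply(function(g, t, o)
    any(ps$gene_id == g & ps$tf_id == t & ps$offset == o &
          ps$sp > 0.999),
    gtp$gene_id, gtp$tf_id, gtp$offset)
  expect_true(all(found))
  expect_length(fx$profiles$skipped, 0L)
  # site ranks: sp non-increasing within each (gene, tf)
  bad <- vapply(split(ps$sp, paste(ps$gene_id, ps$tf_id)),
                function(x) any(diff(x) > 1e-12), TRUE)
  expect_false(any(bad))
})
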