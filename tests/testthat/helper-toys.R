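# small builders shared across the suite

siteRow <- function(gene, tf, rank = 1L, offset = 0L, strand = "+",
                    sp = 1, rep = NA_character_, sq = NA_real_) {
  data.frame(gene_id = gene, tf_id = tf, site_rank = as.integer(rank),
             offset = as.integer(offset), strand = strand, sp = sp,
             repressor_id = rep, sq = sq, stringsAsFactors = FALSE)
}

# a model over an explicit site table; roster defaults to all gene ids
# so every factor's gene exists
tinyModel <- function(prom, body = NULL, roster = NULL,
                      repressorOnly = character(),
                      params = modelParams(a = 10, kc = 1, d = 1)) {
  if (is.null(roster))
    roster <- sort(unique(c(prom$gene_id, prom$tf_id)))
  trnModel(prom, body, roster = roster, repressorOnly = repressorOnly,
           params = params)
}

# consensus-motif PFM: strong counts on the consensus base
consensusPFM <- function(consensus, strong = 43, weak = 1) {
  bases <- c("A", "C", "G", "T")
  wd <- nchar(consensus)
  m <- matrix(weak, 4L, wd, dimnames = list(bases, NULL))
  hit <- match(strsplit(consensus, "")[[1L]], bases)
  m[cbind(hit, seq_len(wd))] <- strong
  m
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# independent naive window scorer used as the motif-scan oracle: scores
# every window on both strands directly from the weight matrix
naiveScan <- function(seq, sm) {
  w <- sm@weights
  wd <- ncol(w)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars) - wd + 1L
  if (n < 1L)
    return(data.frame(offset = integer(), strand = character(),
                      sp = numeric()))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score1 <- function(win) {
    s <- 0
    for (i in seq_len(wd)) {
      b <- win[i]
      s <- s + if (b %in% rownames(w)) w[b, i] else min(w[, i])
    }
    s
  }
  out <- lapply(seq_len(n), function(j) {
    win <- chars[j:(j + wd - 1L)]
    rc <- rev(unname(comp[win]))
    data.frame(offset = j - 1L, strand = c("+", "-"),
               sp = c(score1(win), score1(rc)))
  })
  do.call(rbind, out)
}

# greedy top-k non-overlapping selection on a naive scan, mirroring the
# documented tie-breaks (score desc, offset asc, '+' before '-')
naiveTopSites <- function(scan, wd, k = 4L, floor = 0) {
  scan <- scan[scan$sp >= floor, , drop = FALSE]
  scan <- scan[order(-scan$sp, scan$offset, scan$strand), , drop = FALSE]
  picked <- scan[0, ]
  for (i in seq_len(nrow(scan))) {
    if (!nrow(picked) ||
        all(abs(picked$offset - scan$offset[i]) >= wd)) {
      picked <- rbind(picked, scan[i, ])
      if (nrow(picked) >= k) break
    }
  }
  rownames(picked) <- NULL
  picked
}

# small fixture shared by heavier tests (cached per test run)
smallFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateFixture(fixtureConfig(
        nTfs = 8L, nGenes = 12L, promoterLength = 400L, seed = 11L))
    cache
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
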