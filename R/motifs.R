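#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

.scoreMatrixConsensus <- function(sm) {
  paste(.BASES[apply(sm@weights, 2L, which.max)], collapse = "")
}

#' Read motifs in JASPAR PFM text format
#'
#' Parses the JASPAR text format (`>ID name` header followed by four
#' `A [ ... ]` count rows; bare four-row blocks without brackets are also
#' accepted) and normalises each position frequency matrix with
#' [pfmToScoreMatrix()]. Degenerate matrices, whose best and worst window
#' scores coincide, carry no sequence preference and are dropped with a
#' warning.
#'
#' @param path JASPAR-format text file.
#' @param pseudocount,background passed to [pfmToScoreMatrix()].
#' @param dropDegenerate drop degenerate matrices with a warning instead
#'   of failing.
#' @return named list of [ScoreMatrix-class] objects.
#' @export
readJasparMatrices <- function(path, pseudocount = 0.8,
                               background = rep(0.25, 4),
                               dropDegenerate = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads))
    stop("no '>' headers found in ", path)
  out <- list()
  for (k in seq_along(heads)) {
    from <- heads[k] + 1L
    to <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L)
      stop("motif block with fewer than 4 rows in ", path)
    id <- strsplit(sub("^>\\s*", "", lines[heads[k]]), "\\s+")[[1L]]
    id <- if (length(id) > 1L) id[2L] else id[1L]
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged motif block for ", id, " in ", path)
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- .BASES
    sm <- tryCatch(
      pfmToScoreMatrix(pfm, id, pseudocount, background),
      trnDegenerateMatrix = function(e) {
        if (!dropDegenerate) stop(e)
        warning("dropping degenerate matrix ", id, call. = FALSE)
        NULL
      })
    if (!is.null(sm)) out[[id]] <- sm
  }
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' @param pfms named list of 4 x width count matrices (rows A, C, G, T).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeJasparMatrices <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    m <- pfms[[id]]
    writeLines(sprintf(">%s %s", id, id), con)
    for (b in .BASES)
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Normalise a position frequency matrix to a score matrix
#'
#' Counts are converted to log-odds against the background with a
#' pseudocount, then min-max rescaled per matrix so that the best possible
#' window scores exactly 1 and the worst exactly 0; any window score is
#' the sum of per-position weights and lies in \[0, 1\].
#'
#' @param pfm numeric 4 x width count matrix, rows A, C, G, T.
#' @param tfId identifier attached to the result.
#' @param pseudocount added (spread by background) to each column's
#'   counts; default 0.8.
#' @param background base composition, length 4, summing to 1.
#' @return a [ScoreMatrix-class].
#' @examples
#' pfm <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A","C","G","T")))
#' pfmToScoreMatrix(pfm, "toy")  # window "A" scores 1, others 0
#' @export
pfmToScoreMatrix <- function(pfm, tfId = "TF", pseudocount = 0.8,
                             background = rep(0.25, 4)) {
  if (is.null(dim(pfm)) || nrow(pfm) != 4L || ncol(pfm) < 1L)
    stop("pfm must be a 4 x width matrix with at least one position")
  if (any(pfm < 0) || any(!is.finite(pfm)))
    stop("pfm counts must be finite and non-negative")
  zero <- which(colSums(pfm) == 0)
  if (length(zero))
    stop("all-zero column at position ", zero[1L])
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0))
    stop("background must be positive and sum to 1")
  p <- sweep(pfm + pseudocount * background, 2L,
             colSums(pfm) + pseudocount, "/")
  lo <- log2(p / background)
  cmin <- apply(lo, 2L, min)
  cmax <- apply(lo, 2L, max)
  span <- sum(cmax - cmin)
  if (span <= 1e-12) {
    cond <- simpleCondition(
      sprintf("degenerate matrix '%s': best and worst windows score equally",
              tfId))
    class(cond) <- c("trnDegenerateMatrix", "error", "condition")
    stop(cond)
  }
  w <- sweep(lo, 2L, cmin, "-") / span
  dimnames(w) <- list(.BASES, NULL)
  new("ScoreMatrix", tfId = as.character(tfId), weights = w)
}

# integer-encode a sequence; codes 1..4 = A,C,G,T, 5 = N/other
.encodeSeq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1L]]
  code <- match(v, .BASES)
  code[is.na(code)] <- 5L
  code
}

# window scores at every offset of an encoded sequence under a weight
# matrix extended with a 5th zero row (N scores the per-position minimum,
# which is 0 after normalisation)
.windowScores <- function(code, w) {
  wd <- ncol(w)
  n <- length(code) - wd + 1L
  if (n < 1L) return(numeric(0))
  w5 <- rbind(w, 0)
  acc <- numeric(n)
  for (i in seq_len(wd))
    acc <- acc + w5[code[seq_len(n) + (i - 1L)], i]
  acc
}

.revcompWeights <- function(w) {
  # scoring the + strand with this equals scoring the reverse complement
  # window with the original matrix
  w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
}

#' Scan a sequence with a score matrix
#'
#' Scores every window on both strands and greedily retains up to
#' `nSites` non-overlapping sites by descending score (ties broken by
#' offset, then '+' strand), so one high-scoring run cannot be counted
#' several times. Sequences shorter than the motif yield an empty result.
#'
#' @param seq a character DNA sequence over A, C, G, T, N (N scores the
#'   per-position minimum).
#' @param sm a [ScoreMatrix-class].
#' @param nSites maximum sites retained (default 4).
#' @param floor sites scoring below this are not reported (default 0).
#' @return data.frame with columns `offset` (0-based within `seq`),
#'   `strand`, `sp`, ordered by descending `sp`.
#' @export
scanRegion <- function(seq, sm, nSites = 4L, floor = 0) {
  stopifnot(is(sm, "ScoreMatrix"))
  code <- .encodeSeq(seq)
  wd <- ncol(sm@weights)
  fw <- .windowScores(code, sm@weights)
  rv <- .windowScores(code, .revcompWeights(sm@weights))
  if (!length(fw))
    return(data.frame(offset = integer(), strand = character(),
                      sp = numeric()))
  cand <- data.frame(
    offset = c(seq_along(fw), seq_along(rv)) - 1L,
    strand = rep(c("+", "-"), c(length(fw), length(rv))),
    sp = c(fw, rv))
  cand <- cand[cand$sp >= floor, , drop = FALSE]
  ord <- order(-cand$sp, cand$offset, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  sel <- integer()
  for (i in seq_len(nrow(cand))) {
    o <- cand$offset[i]
    if (!length(sel) ||
        all(abs(cand$offset[sel] - o) >= wd)) {
      sel <- c(sel, i)
      if (length(sel) >= nSites) break
    }
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the strongest competing repressor for a binding site
#'
#' Every other factor is scored on windows overlapping the site (both
#' strands); its competition criterion is `10^(-a (1 - Sq)) * [R] / Ki`.
#' The maximiser is attached as the site's repressor, with ties broken by
#' lexicographically smallest factor id. When `floor` is not `NULL` and
#' the best criterion falls below it, no repressor is attached.
#'
#' @param tfId factor owning the site (excluded from candidates).
#' @param seq the region sequence containing the site.
#' @param offset 0-based site start within `seq`.
#' @param width site width (the owner motif's width).
#' @param matrices named list of [ScoreMatrix-class] candidates.
#' @param concentrations named numeric of candidate concentrations.
#' @param ki named numeric of inhibition constants (default 1 for all).
#' @param a score weighting exponent.
#' @param floor criterion floor; `NULL` recomputes the default, the
#'   criterion value at Sq = 0.5 with the median concentration and median
#'   Ki.
#' @return list with `repressor_id` and `sq` (both `NA` when no candidate
#'   qualifies).
#' @export
selectRepressor <- function(tfId, seq, offset, width, matrices,
                            concentrations, ki = NULL, a = 10,
                            floor = NULL) {
  cand <- setdiff(names(matrices), tfId)
  if (!length(cand))
    return(list(repressor_id = NA_character_, sq = NA_real_))
  if (is.null(ki))
    ki <- stats::setNames(rep(1, length(cand)), cand)
  code <- .encodeSeq(seq)
  sq <- vapply(cand, function(id)
    .bestOverlapScore(code, matrices[[id]]@weights, offset, width), 0)
  crit <- 10^(-a * (1 - sq)) * concentrations[cand] / ki[cand]
  if (is.null(floor))
    floor <- 10^(-a * 0.5) * stats::median(concentrations[cand]) /
      stats::median(ki[cand])
  best <- max(crit)
  if (!is.finite(best) || best < floor || all(sq <= 0))
    return(list(repressor_id = NA_character_, sq = NA_real_))
  hit <- cand[crit == best]
  hit <- sort(hit)[1L]  # deterministic tie-break
  list(repressor_id = hit, sq = unname(sq[hit]))
}

# best window score of a weight matrix over all windows overlapping
# [offset, offset + width) (0-based), both strands
.bestOverlapScore <- function(code, w, offset, width) {
  wc <- ncol(w)
  n <- length(code) - wc + 1L
  if (n < 1L) return(0)
  j0 <- max(0L, offset - wc + 1L)
  j1 <- min(n - 1L, offset + width - 1L)
  if (j0 > j1) return(0)
  idx <- (j0:j1) + 1L
  fw <- .windowScores(code, w)
  rv <- .windowScores(code, .revcompWeights(w))
  max(fw[idx], rv[idx])
}

# ---- region scanning ------------------------------------------------------
#
# Scanning is split in two stages so the expensive sequence pass can be
# shared: .scanRegionSites() finds each factor's top sites and every
# candidate's best overlapping score (Sq) — all concentration-independent
# — and .attachRepressors() ranks candidates by the competition criterion
# for a given concentration vector.

.pmax2 <- function(a, b) {  # dispatch-free parallel max
  i <- b > a
  a[i] <- b[i]
  a
}

# left-aligned rolling max over window k in O(n): block prefix/suffix
# maxima (van Herk); window j spans the suffix of its block and the
# prefix of the next
.rollMaxLeft <- function(x, k) {
  N <- length(x)
  nOut <- N - k + 1L
  if (k == 1L) return(x)
  nb <- ceiling(N / k)
  xp <- c(x, rep(-Inf, nb * k - N))
  A <- matrix(xp, nrow = k)
  SUF <- A
  for (i in (k - 1L):1L)
    SUF[i, ] <- .pmax2(SUF[i, ], SUF[i + 1L, ])
  PRE <- A
  for (i in 2:k)
    PRE[i, ] <- .pmax2(PRE[i, ], PRE[i - 1L, ])
  j <- seq_len(nOut)
  e <- j + k - 1L
  .pmax2(SUF[cbind((j - 1L) %% k + 1L, (j - 1L) %/% k + 1L)],
         PRE[cbind((e - 1L) %% k + 1L, (e - 1L) %/% k + 1L)])
}

# sites + candidate Sq matrices for one region sequence
.scanRegionSites <- function(seq, matrices, params) {
  code <- .encodeSeq(seq)
  ids <- names(matrices)
  nTf <- length(ids)
  idsLex <- ids[order(ids)]
  fwAll <- lapply(matrices, function(m) .windowScores(code, m@weights))
  rvAll <- lapply(matrices, function(m)
    .windowScores(code, .revcompWeights(m@weights)))
  bothMax <- Map(.pmax2, fwAll, rvAll)
  widths <- vapply(matrices, function(m) ncol(m@weights), 0L)
  rolledCache <- new.env(parent = emptyenv())
  # rolled[j+1] = best score of candidate c2 over windows overlapping a
  # width-wd site starting at 0-based offset j
  rolledFor <- function(c2, wd, nOwn) {
    key <- paste0(c2, "_", wd)
    got <- rolledCache[[key]]
    if (!is.null(got)) return(got)
    bm <- bothMax[[c2]]
    wc <- widths[c2]
    n2 <- length(bm)
    if (n2 < 1L) {
      out <- rep(0, nOwn)
    } else {
      xp <- c(rep(-Inf, wc - 1L), bm,
              rep(-Inf, wd - 1L + max(0L, nOwn - n2)))
      out <- .rollMaxLeft(xp, wc + wd - 1L)
      out[!is.finite(out)] <- 0
    }
    rolledCache[[key]] <- out
    out
  }
  res <- vector("list", nTf)
  sqs <- vector("list", nTf)
  for (t in seq_len(nTf)) {
    id <- ids[t]
    wd <- widths[t]
    fw <- fwAll[[t]]
    n <- length(fw)
    if (!n) next
    sp <- c(fw, rvAll[[t]])
    keep <- which(sp >= params@scoreFloor)
    if (!length(keep)) next
    off <- (keep - 1L) %% n
    minus <- keep > n
    ord <- order(-sp[keep], off, minus)
    sel <- integer()
    for (i in ord) {
      if (!length(sel) || all(abs(off[sel] - off[i]) >= wd)) {
        sel <- c(sel, i)
        if (length(sel) >= params@pMax) break
      }
    }
    nr <- length(sel)
    siteOff <- off[sel]
    if (nTf > 1L) {
      sqMat <- vapply(idsLex, function(c2) {
        if (c2 == id) return(rep(0, nr))
        rolledFor(c2, wd, n)[siteOff + 1L]
      }, numeric(nr))
      if (nr == 1L) sqMat <- matrix(sqMat, nrow = 1L,
                                    dimnames = list(NULL, idsLex))
    } else {
      sqMat <- matrix(0, nr, 0L)
    }
    res[[t]] <- data.frame(
      tf_id = id, site_rank = seq_len(nr), offset = siteOff,
      strand = c("+", "-")[minus[sel] + 1L], sp = sp[keep][sel],
      stringsAsFactors = FALSE)
    sqs[[t]] <- sqMat
  }
  got <- !vapply(res, is.null, TRUE)
  list(sites = do.call(rbind, res[got]),
       sqMat = do.call(rbind, sqs[got]), idsLex = idsLex)
}

# rank candidates by 10^(-a(1-Sq)) * [R] / Ki and attach the best one
.attachRepressors <- function(scan, conc, ki, a, repFloor) {
  sites <- scan$sites
  if (is.null(sites) || !nrow(sites)) return(sites)
  nr <- nrow(sites)
  rid <- rep(NA_character_, nr)
  rsq <- rep(NA_real_, nr)
  idsLex <- scan$idsLex
  if (length(idsLex) > 1L) {
    critMat <- 10^(-a * (1 - scan$sqMat)) *
      rep(conc[idsLex] / ki[idsLex], each = nr)
    critMat[cbind(seq_len(nr), match(sites$tf_id, idsLex))] <- -Inf
    critMat[scan$sqMat <= 0] <- -Inf
    bestCol <- max.col(critMat, ties.method = "first")
    bestCrit <- critMat[cbind(seq_len(nr), bestCol)]
    ok <- is.finite(bestCrit) & bestCrit >= repFloor
    rid[ok] <- idsLex[bestCol[ok]]
    rsq[ok] <- scan$sqMat[cbind(which(ok), bestCol[ok])]
  }
  sites$repressor_id <- rid
  sites$sq <- rsq
  sites
}

# scan every promoter and gene-body region once
# (concentration-independent stage of buildBindingProfiles)
.profileScan <- function(annotation, genome, matrices, params) {
  if (is.character(genome))
    genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  extract <- function(gr) {
    chr <- as.character(seqnames(gr))
    if (!chr %in% names(genome)) return(NULL)
    sq <- genome[[chr]]
    if (end(gr) > length(sq)) return(NULL)
    as.character(subseq(sq, start(gr), end(gr)))
  }
  prom <- list(); body <- list(); skipped <- character()
  promGR <- annotation@promoters
  for (gid in names(promGR)) {
    seq <- extract(promGR[gid])
    if (is.null(seq)) { skipped <- c(skipped, gid); next }
    prom[[gid]] <- c(.scanRegionSites(seq, matrices, params),
                     list(start0 = start(promGR[gid]) - 1L))
    bodies <- annotation@geneBodies[[gid]]
    if (is.null(bodies) || !length(bodies)) next
    parts <- list()
    for (b in seq_along(bodies)) {
      bseq <- extract(bodies[b])
      if (is.null(bseq)) next
      parts[[length(parts) + 1L]] <-
        c(.scanRegionSites(bseq, matrices, params),
          list(start0 = start(bodies[b]) - 1L))
    }
    if (length(parts)) body[[gid]] <- parts
  }
  list(prom = prom, body = body, skipped = skipped)
}

# attach repressors and assemble the final site tables
.assembleProfiles <- function(scanned, conc, ki, params,
                              selectRepressors = TRUE) {
  repFloor <- 10^(-params@a * 0.5) * stats::median(conc) /
    stats::median(ki)
  finish <- function(scan) {
    if (is.null(scan$sites) || !nrow(scan$sites)) return(NULL)
    df <- if (selectRepressors)
      .attachRepressors(scan, conc, ki, params@a, repFloor)
    else {
      out <- scan$sites
      out$repressor_id <- NA_character_
      out$sq <- NA_real_
      out
    }
    df$offset <- df$offset + scan$start0
    df
  }
  promRows <- list(); bodyRows <- list()
  for (gid in names(scanned$prom)) {
    df <- finish(scanned$prom[[gid]])
    if (!is.null(df))
      promRows[[gid]] <- cbind(gene_id = gid, df,
                               stringsAsFactors = FALSE)
  }
  for (gid in names(scanned$body)) {
    parts <- lapply(scanned$body[[gid]], finish)
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) next
    bd <- do.call(rbind, parts)
    # re-rank: top pMax per factor across the gene's body regions
    bd <- bd[order(bd$tf_id, -bd$sp, bd$offset), , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(bd)), bd$tf_id),
                          function(i)
                            i[seq_len(min(length(i), params@pMax))]),
                   use.names = FALSE)
    bd <- bd[sort(keep), , drop = FALSE]
    bd$site_rank <- unlist(lapply(split(bd$sp, bd$tf_id), seq_along),
                           use.names = FALSE)
    bodyRows[[gid]] <- cbind(gene_id = gid, bd,
                             stringsAsFactors = FALSE)
  }
  bind <- function(rows) {
    if (!length(rows)) return(emptySiteFrame())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, .SITE_COLS]
  }
  list(promoterSites = bind(promRows), geneBodySites = bind(bodyRows),
       skipped = scanned$skipped)
}

#' Build promoter and gene-body binding profiles
#'
#' Scans every annotated promoter and gene-body region with every score
#' matrix, keeps the top-4 non-overlapping sites per factor and region
#' class above the score floor, and attaches each site's strongest
#' competing repressor. Repressor selection uses the supplied (initial
#' state) concentrations, computed once, so the network topology stays
#' fixed during later optimisation. For gene bodies the top 4 sites per
#' factor are taken across the gene's body regions jointly.
#'
#' @param annotation a [RegionAnnotation-class].
#' @param genome a `DNAStringSet` (or FASTA path) with the region
#'   sequences' chromosomes.
#' @param matrices named list of [ScoreMatrix-class].
#' @param concentrations named numeric of factor concentrations from the
#'   initial expression table.
#' @param ki optional named numeric of inhibition constants (default 1
#'   per factor).
#' @param params a [ModelParams-class]; `scoreFloor` and `a` are used
#'   here.
#' @param selectRepressors set `FALSE` to skip repressor attachment.
#' @return list with data.frames `promoterSites` and `geneBodySites`
#'   (columns `gene_id, tf_id, site_rank, offset, strand, sp,
#'   repressor_id, sq`; offsets are genomic 0-based starts) plus
#'   `skipped`, gene ids lacking an extractable promoter sequence.
#' @export
buildBindingProfiles <- function(annotation, genome, matrices,
                                 concentrations, ki = NULL,
                                 params = modelParams(),
                                 selectRepressors = TRUE) {
  ids <- names(matrices)
  conc <- concentrations[ids]
  if (any(is.na(conc)))
    stop("concentrations missing for: ",
         paste(ids[is.na(conc)], collapse = ", "))
  names(conc) <- ids
  if (is.null(ki))
    ki <- stats::setNames(rep(1, length(ids)), ids)
  ki <- ki[ids]
  scanned <- .profileScan(annotation, genome, matrices, params)
  .assembleProfiles(scanned, conc, ki, params, selectRepressors)
}

#' Write / read a binding-site table
#'
#' Plain CSV with the columns `gene_id, tf_id, site_rank, offset, strand,
#' sp, repressor_id, sq`. Writing is deterministic (fixed row and column
#' order, full precision) so identical inputs give byte-identical files.
#'
#' @param sites a binding-site data.frame.
#' @param path CSV path.
#' @return `writeBindingSites()` returns `path` invisibly;
#'   `readBindingSites()` the data.frame.
#' @export
writeBindingSites <- function(sites, path) {
  df <- sites[order(sites$gene_id, sites$tf_id, sites$site_rank),
              .SITE_COLS, drop = FALSE]
  df$sp <- sprintf("%.15g", df$sp)
  df$sq <- ifelse(is.na(df$sq), "", sprintf("%.15g", df$sq))
  df$repressor_id[is.na(df$repressor_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBindingSites
#' @export
readBindingSites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          gene_id = "character", tf_id = "character",
                          site_rank = "integer", offset = "integer",
                          strand = "character", sp = "numeric",
                          repressor_id = "character", sq = "numeric"))
  df$repressor_id[!nzchar(df$repressor_id)] <- NA_character_
  df
}
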