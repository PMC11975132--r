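#' @include AllClasses.R
NULL

.ASSAYS <- c("histone_chip", "dnase", "atac")

#' Coerce peak input to a GRanges with an assay label
#'
#' Accepts a `GRanges` with an `assay` metadata column, or a data.frame
#' with columns `chrom`, `start`, `end` (0-based half-open, BED
#' convention) and `assay`. Malformed records (start >= end, unknown
#' assay) raise an error naming the record.
#' @noRd
.asPeaks <- function(peaks) {
  if (is(peaks, "GRanges")) {
    if (is.null(peaks$assay))
      stop("peak GRanges must carry an 'assay' metadata column")
    gr <- peaks
  } else if (is.data.frame(peaks)) {
    need <- c("chrom", "start", "end", "assay")
    miss <- setdiff(need, names(peaks))
    if (length(miss))
      stop("peak data.frame lacks columns: ", paste(miss, collapse = ", "))
    bad <- which(peaks$start >= peaks$end)
    if (length(bad))
      stop(sprintf(
        "malformed interval (start >= end) in peak record %d: %s:%d-%d",
        bad[1L], peaks$chrom[bad[1L]], peaks$start[bad[1L]],
        peaks$end[bad[1L]]))
    gr <- GRanges(peaks$chrom,
                  IRanges(peaks$start + 1L, peaks$end),
                  assay = as.character(peaks$assay))
  } else {
    stop("peaks must be a GRanges or a data.frame")
  }
  bad <- setdiff(unique(gr$assay), .ASSAYS)
  if (length(bad))
    stop("unknown assay label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.ASSAYS, collapse = ", "), ")")
  gr
}

#' Call open-chromatin regions from per-assay peaks
#'
#' Open regions are the maximal unions of overlapping-or-abutting
#' (book-ended) positive intervals across all assays, keeping only unions
#' supported by at least one accessibility interval (DNase-seq or
#' ATAC-seq). Histone-mark-only unions are dropped: heterochromatin-dense
#' regions without accessibility never become open.
#'
#' @param peaks a `GRanges` with metadata column `assay` (one of
#'   `"histone_chip"`, `"dnase"`, `"atac"`), or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open), `assay`.
#' @return a sorted, disjoint `GRanges` of open regions.
#' @examples
#' pk <- data.frame(chrom = "chr1", start = c(100, 150), end = c(200, 250),
#'                  assay = c("histone_chip", "atac"))
#' callOpenRegions(pk)  # one open region 100-250
#' @export
callOpenRegions <- function(peaks) {
  gr <- .asPeaks(peaks)
  if (!length(gr))
    return(GenomicRanges::sort(GRanges()))
  merged <- reduce(gr, ignore.strand = TRUE)  # merges book-ended runs
  acc <- gr[gr$assay %in% c("dnase", "atac")]
  keep <- overlapsAny(merged, acc, ignore.strand = TRUE)
  GenomicRanges::sort(merged[keep])
}

#' Coerce gene-model input to an oriented GRanges
#'
#' Accepts a `GRanges` with `gene_id` (strand gives direction; TSS is the
#' 5' end) or a data.frame with columns `gene_id`, `chrom`, `strand`,
#' `tss`, `tes` (0-based positions).
#' @noRd
.asGenes <- function(genes) {
  if (is(genes, "GRanges")) {
    if (is.null(genes$gene_id))
      stop("gene GRanges must carry a 'gene_id' metadata column")
    if (any(!as.character(strand(genes)) %in% c("+", "-")))
      stop("gene strand must be '+' or '-'")
    return(genes)
  }
  if (!is.data.frame(genes))
    stop("genes must be a GRanges or a data.frame")
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene data.frame lacks columns: ", paste(miss, collapse = ", "))
  if (any(genes$tss == genes$tes))
    stop("gene with tss == tes: ",
         genes$gene_id[which(genes$tss == genes$tes)[1L]])
  plus <- genes$strand == "+"
  if (any(plus & genes$tss >= genes$tes) ||
      any(!plus & genes$tss <= genes$tes))
    stop("tss/tes order inconsistent with strand")
  lo <- pmin(genes$tss, genes$tes)
  hi <- pmax(genes$tss, genes$tes)
  GRanges(genes$chrom, IRanges(lo + 1L, hi), strand = genes$strand,
          gene_id = genes$gene_id)
}

.tssPos <- function(genes) {
  # 1-based TSS position: 5' end of the oriented range
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' Classify open regions into promoters and gene-body regions
#'
#' For each gene the promoter is the open region containing its
#' transcription start site (TSS containment uses the half-open BED rule:
#' a TSS sitting exactly on a region's end coordinate is outside).
#' Gene-body regions are the intersections of open regions with the
#' TSS-to-TES span, with any promoter overlap removed. Genes whose TSS
#' falls in no open region are flagged excluded from the network.
#'
#' @param openRegions disjoint `GRanges` from [callOpenRegions()].
#' @param genes a `GRanges` with metadata `gene_id` (strand-oriented; the
#'   TSS is the 5' end), or a data.frame with columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `tes` (0-based positions).
#' @return a [RegionAnnotation-class].
#' @export
classifyRegions <- function(openRegions, genes) {
  genes <- .asGenes(genes)
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id")
  openRegions <- GenomicRanges::sort(reduce(openRegions,
                                            ignore.strand = TRUE))
  tss <- GRanges(seqnames(genes), IRanges(.tssPos(genes), width = 1L))
  hit <- findOverlaps(tss, openRegions, ignore.strand = TRUE)
  promIdx <- rep(NA_integer_, length(genes))
  promIdx[queryHits(hit)] <- subjectHits(hit)

  hasProm <- !is.na(promIdx)
  prom <- openRegions[promIdx[hasProm]]
  names(prom) <- genes$gene_id[hasProm]

  # gene bodies: open regions intersected with the TSS-TES span, promoter
  # overlap removed. The promoter IS one of the disjoint open regions, so
  # this equals the intersections with every open region except it.
  spans <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)))
  bh <- findOverlaps(spans, openRegions, ignore.strand = TRUE)
  qi <- queryHits(bh); si <- subjectHits(bh)
  keep <- hasProm[qi] & si != promIdx[qi]
  qi <- qi[keep]; si <- si[keep]
  pieces <- GRanges(seqnames(genes)[qi],
                    IRanges(pmax(start(spans)[qi], start(openRegions)[si]),
                            pmin(end(spans)[qi], end(openRegions)[si])))
  bodies <- GenomicRanges::split(
    pieces, factor(genes$gene_id[qi], levels = genes$gene_id[hasProm]))

  new("RegionAnnotation", genes = genes, promoters = prom,
      geneBodies = bodies, excluded = genes$gene_id[!hasProm])
}

#' Read per-assay peak BED files
#'
#' @param histone,dnase,atac character vectors of BED file paths per
#'   assay (each may be empty).
#' @return a `GRanges` with an `assay` metadata column, suitable for
#'   [callOpenRegions()]. Errors if no accessibility (dnase/atac) file is
#'   given, since the open-region definition is then unsatisfiable.
#' @export
readPeakBeds <- function(histone = character(), dnase = character(),
                         atac = character()) {
  if (!length(dnase) && !length(atac))
    stop("at least one DNase-seq or ATAC-seq BED is required: ",
         "open regions need accessibility support")
  one <- function(paths, assay) {
    if (!length(paths)) {
      gr0 <- GRanges()
      gr0$assay <- character(0)
      return(gr0)
    }
    grs <- lapply(paths, function(p) {
      gr <- rtracklayer::import(p, format = "BED")
      S4Vectors::mcols(gr) <- NULL
      gr
    })
    gr <- do.call(c, grs)
    gr$assay <- assay
    gr
  }
  out <- c(one(histone, "histone_chip"), one(dnase, "dnase"),
           one(atac, "atac"))
  strand(out) <- "*"
  out
}

#' Read gene models from GTF/GFF3
#'
#' Keeps features of type `gene` (or `transcript` when no gene features
#' are present) and extracts `gene_id` (falling back to `ID`/`Name`).
#'
#' @param path GTF or GFF3 file.
#' @return oriented `GRanges` with metadata column `gene_id`.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    sel <- gr[gr$type == "gene"]
    if (!length(sel)) sel <- gr[gr$type == "transcript"]
    if (length(sel)) gr <- sel
  }
  id <- gr$gene_id
  if (is.null(id)) id <- gr$ID
  if (is.null(id)) id <- gr$Name
  if (is.null(id))
    stop("no gene_id/ID/Name attribute found in ", path)
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr), gene_id = as.character(id))
  if (any(!as.character(strand(out)) %in% c("+", "-")))
    stop("gene records without strand in ", path)
  out
}

.fmtRegion <- function(gr) {
  # text form in BED convention: chrom:start-end, 0-based half-open
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

.parseRegion <- function(txt) {
  m <- regmatches(txt, regexec("^(.+):([0-9]+)-([0-9]+)$", txt))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed region string: ", txt[bad][1L])
  chrom <- vapply(m, `[`, "", 2L)
  s <- as.integer(vapply(m, `[`, "", 3L))
  e <- as.integer(vapply(m, `[`, "", 4L))
  GRanges(chrom, IRanges(s + 1L, e))
}

#' Write / read a region annotation table
#'
#' Tab-separated with columns `gene_id`, `promoter` (chrom:start-end in
#' BED convention, empty if absent) and `gene_body_regions`
#' (semicolon-joined). `readRegionAnnotation()` restores a
#' [RegionAnnotation-class] given the same gene models.
#'
#' @param annotation a [RegionAnnotation-class].
#' @param path output TSV path.
#' @return `writeRegionAnnotation()` returns `path` invisibly;
#'   `readRegionAnnotation()` returns a [RegionAnnotation-class].
#' @export
writeRegionAnnotation <- function(annotation, path) {
  g <- annotation@genes
  prom <- rep("", length(g))
  hasP <- g$gene_id %in% names(annotation@promoters)
  prom[hasP] <- .fmtRegion(annotation@promoters[g$gene_id[hasP]])
  body <- vapply(g$gene_id, function(id) {
    if (!id %in% names(annotation@geneBodies)) return("")
    b <- annotation@geneBodies[[id]]
    if (!length(b)) return("")
    paste(.fmtRegion(b), collapse = ";")
  }, "")
  df <- data.frame(gene_id = g$gene_id, promoter = prom,
                   gene_body_regions = body, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionAnnotation
#' @param genes gene models (`GRanges` or data.frame) matching the table.
#' @export
readRegionAnnotation <- function(path, genes) {
  genes <- .asGenes(genes)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  df$promoter[is.na(df$promoter)] <- ""
  df$gene_body_regions[is.na(df$gene_body_regions)] <- ""
  hasP <- nzchar(df$promoter)
  prom <- .parseRegion(df$promoter[hasP])
  names(prom) <- df$gene_id[hasP]
  bodies <- GRangesList(lapply(which(hasP), function(i) {
    if (!nzchar(df$gene_body_regions[i])) return(GRanges())
    .parseRegion(strsplit(df$gene_body_regions[i], ";")[[1L]])
  }))
  names(bodies) <- df$gene_id[hasP]
  new("RegionAnnotation", genes = genes, promoters = prom,
      geneBodies = bodies, excluded = df$gene_id[!hasP])
}
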