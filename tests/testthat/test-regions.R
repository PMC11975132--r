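test_that("open regions merge connected peaks across assays and require accessibility", {
  pk <- data.frame(
    chrom = "chr1",
    start = c(100, 150, 400, 600),
    end = c(200, 250, 500, 700),
    assay = c("histone_chip", "atac", "histone_chip", "dnase"))
  open <- callOpenRegions(pk)
  # histone [100,200) + atac [150,250) merge and keep accessibility;
  # histone-only [400,500) is dropped; dnase alone stands
  expect_equal(start(open) - 1L, c(100, 600))
  expect_equal(end(open), c(250, 700))

  histOnly <- callOpenRegions(
    data.frame(chrom = "chr1", start = 100, end = 200,
               assay = "histone_chip"))
  expect_length(histOnly, 0L)
  expect_length(callOpenRegions(
    data.frame(chrom = character(), start = integer(), end = integer(),
               assay = character())), 0L)
})

test_that("book-ended peaks are connected, disjoint peaks are not", {
  pk <- data.frame(chrom = "chr1", start = c(100, 200, 301),
                   end = c(200, 300, 400),
                   assay = c("histone_chip", "atac", "atac"))
  open <- callOpenRegions(pk)
  expect_equal(start(open) - 1L, c(100, 301))
  expect_equal(end(open), c(300, 400))
})

test_that("malformed peak records are rejected with the record named", {
  bad <- data.frame(chrom = "chr1", start = c(10, 50), end = c(20, 40),
                    assay = "atac")
  expect_error(callOpenRegions(bad), "start >= end")
  expect_error(callOpenRegions(bad), "record 2")
  expect_error(callOpenRegions(
    data.frame(chrom = "chr1", start = 1, end = 5, assay = "rna")),
    "unknown assay")
})

# brute-force oracle: mark every covered bp, take connected runs, keep
# runs containing at least one accessible bp
bruteOpen <- function(pk, len = 10000L) {
  cov <- logical(len); acc <- logical(len)
  for (i in seq_len(nrow(pk))) {
    idx <- (pk$start[i] + 1L):pk$end[i]
    cov[idx] <- TRUE
    if (pk$assay[i] %in% c("dnase", "atac")) acc[idx] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(ends), function(k)
    any(acc[starts[k]:ends[k]]), TRUE)
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

test_that("open-region calling equals per-base-pair brute force", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    s <- sample(0:9900, n, TRUE)
    pk <- data.frame(chrom = "c", start = s,
                     end = s + sample(10:400, n, TRUE),
                     assay = sample(c("histone_chip", "dnase", "atac"),
                                    n, TRUE))
    pk$end <- pmin(pk$end, 10000L)
    open <- callOpenRegions(pk)
    ref <- bruteOpen(pk)
    expect_equal(start(open) - 1L, ref$start)
    expect_equal(end(open), ref$end)
  }
})

test_that("promoters contain the TSS under the half-open rule", {
  open <- callOpenRegions(data.frame(
    chrom = "chr1", start = c(100, 400), end = c(250, 500),
    assay = "atac"))
  genes <- data.frame(
    gene_id = c("gIn", "gBoundaryStart", "gBoundaryEnd", "gOut"),
    chrom = "chr1", strand = "+",
    tss = c(180L, 100L, 250L, 300L),
    tes = c(600L, 600L, 600L, 600L))
  ann <- classifyRegions(open, genes)
  prom <- genePromoters(ann)
  expect_setequal(names(prom), c("gIn", "gBoundaryStart"))
  expect_equal(unname(start(prom["gIn"]) - 1L), 100)
  expect_equal(unname(end(prom["gIn"])), 250)
  # TSS exactly at region end (half-open) and TSS in a gap are excluded
  expect_setequal(excludedGenes(ann), c("gBoundaryEnd", "gOut"))
})

test_that("gene bodies are open regions in the span minus the promoter", {
  open <- callOpenRegions(data.frame(
    chrom = "chr1", start = c(100, 400, 700), end = c(250, 500, 900),
    assay = "atac"))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 180L, tes = 600L)
  ann <- classifyRegions(open, genes)
  bd <- geneBodies(ann)[["g1"]]
  # promoter-resident piece [180,250) is removed entirely; [400,500) is
  # kept; [700,900) is beyond the TES
  expect_equal(start(bd) - 1L, 400)
  expect_equal(end(bd), 500)
  # promoter and bodies never overlap
  expect_length(
    GenomicRanges::intersect(genePromoters(ann)["g1"], bd), 0L)
})

test_that("minus-strand genes use their 5' end as TSS", {
  open <- callOpenRegions(data.frame(
    chrom = "chr1", start = c(700, 200), end = c(900, 300),
    assay = "atac"))
  genes <- data.frame(gene_id = "gm", chrom = "chr1", strand = "-",
                      tss = 800L, tes = 250L)
  ann <- classifyRegions(open, genes)
  expect_equal(unname(start(genePromoters(ann)["gm"]) - 1L), 700)
  bd <- geneBodies(ann)[["gm"]]
  expect_equal(start(bd) - 1L, 250)
  expect_equal(end(bd), 300)
})

test_that("classification is deterministic, idempotent and promoter-disjoint", {
  set.seed(72)
  s <- sample(0:9000, 15)
  open <- callOpenRegions(data.frame(
    chrom = "c", start = s, end = s + sample(50:600, 15, TRUE),
    assay = sample(c("histone_chip", "atac"), 15, TRUE,
                   prob = c(0.3, 0.7))))
  genes <- data.frame(gene_id = paste0("g", 1:10), chrom = "c",
                      strand = "+", tss = sample(0:8000, 10),
                      tes = 9500L + 0:9)
  a1 <- classifyRegions(open, genes)
  a2 <- classifyRegions(open, genes)
  expect_identical(genePromoters(a1), genePromoters(a2))
  for (g in names(genePromoters(a1))) {
    bd <- geneBodies(a1)[[g]]
    if (length(bd))
      expect_length(
        GenomicRanges::intersect(genePromoters(a1)[g], bd), 0L)
  }
})

test_that("adding accessibility peaks never loses promoters", {
  set.seed(73)
  genes <- data.frame(gene_id = paste0("g", 1:12), chrom = "c",
                      strand = "+", tss = sample(0:9000, 12),
                      tes = 9800L + 0:11)
  s <- sample(0:9000, 30)
  pk <- data.frame(chrom = "c", start = s,
                   end = s + sample(50:300, 30, TRUE),
                   assay = sample(c("histone_chip", "dnase", "atac"),
                                  30, TRUE))
  counts <- vapply(seq(5, 30, 5), function(k) {
    ann <- classifyRegions(callOpenRegions(pk[1:k, ]), genes)
    length(genePromoters(ann))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("region annotation tables round-trip through TSV", {
  fx <- smallFixture()
  path <- tempfile(fileext = ".tsv")
  writeRegionAnnotation(fx$annotation, path)
  back <- readRegionAnnotation(path, fx$genes)
  expect_identical(names(genePromoters(back)),
                   names(genePromoters(fx$annotation)))
  expect_equal(start(genePromoters(back)),
               start(genePromoters(fx$annotation)))
  expect_equal(lapply(geneBodies(back), start),
               lapply(geneBodies(fx$annotation), start))
  expect_identical(excludedGenes(back), excludedGenes(fx$annotation))
})

test_that("peak readers demand an accessibility assay", {
  expect_error(readPeakBeds(histone = "x.bed"), "DNase|ATAC")
})
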