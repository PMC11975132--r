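#' @include AllClasses.R regions.R motifs.R model.R
NULL

#' Configuration of the synthetic fixture generator
#'
#' The generator emulates every input the screening pipeline consumes —
#' genome FASTA, gene models, per-assay peak intervals, motifs in JASPAR
#' text format, initial and reference expression tables — at toy scale
#' with a known ground-truth network: each gene's promoter carries
#' planted consensus sites of its designated regulators, and the
#' reference expression state is produced by the forward model itself run
#' to near-fixed-point under the true dissociation constants (so the
#' reference is reachable by the model class), with multiplicative
#' log-normal measurement noise.
#'
#' Regulators are dealt so that every factor regulates the same number of
#' factor genes, which keeps every dissociation constant identifiable.
#'
#' @param nTfs number of transcription factors (each with a motif and a
#'   factor gene named after it).
#' @param nGenes total genes (`>= nTfs`); the surplus are non-factor
#'   target genes that exercise the region and binding stages only.
#' @param promoterLength open promoter length in bp.
#' @param motifWidth motif width in bp (high information content, one
#'   dominant base per position, so planted sites score exactly 1). The
#'   default 12 keeps the best background window around a 3/4 match,
#'   whose exponential site weight is small enough that background sites
#'   stay off throughout the dynamics' operating range.
#' @param regulatorsPerGene planted regulators per gene.
#' @param sitesPerEdge planted consensus copies per regulator and gene.
#' @param nPeripheralTfs number of fully disconnected factors: kept out
#'   of the regulator deck and given no planted regulators of their own
#'   gene, so they neither drive nor receive network regulation and
#'   equilibrate near zero. Real rosters always contain such weakly
#'   connected, lowly expressed factors; they are the ground-truth
#'   non-core factors, and clamping their constant leaves the rest of
#'   the fit untouched (an expressed factor clamped to a very low Kd
#'   would instead ignite its background sites genome-wide).
#' @param trueKd ground-truth dissociation constant (scalar or per
#'   factor).
#' @param perturbedTfs named numeric: fold changes applied to `trueKd`
#'   when generating the reference state (the planted "core" factors).
#' @param repressorOnlyTfs factor ids flagged repressor-only.
#' @param bodyLength gene-body length in bp.
#' @param bodyOpenFraction fraction of factor genes given an open
#'   gene-body region with one planted repressor site.
#' @param noiseSigma log-normal noise sd on the reference expression.
#' @param refSteps forward steps used to produce the reference state.
#' @param params a [ModelParams-class]. The default sets the
#'   super-enhancer trigger above the reachable score sum (with four
#'   listed sites per factor-region pair — two planted plus background —
#'   the score sum always straddles 3, which would flip regimes
#'   per gene at random), so the ground-truth dynamics operate in the
#'   competitive-equilibrium regime; and a degradation rate (2.0) above
#'   the maximal per-gene activation flux `3 kc e^(-1/2)`, so
#'   trajectories are bounded, with unperturbed fixed points around 4
#'   where occupancy is near saturation: losing one of a gene's three
#'   regulators collapses it several-fold while ordinary concentration
#'   fluctuations are damped, so perturbation effects attenuate
#'   geometrically along regulatory cascades.
#' @param seed structural seed; fixed seed gives byte-identical outputs.
#' @param noiseSeed seed for the reference noise only (defaults to
#'   `seed + 7919`); varying it alone leaves all ground-truth tables
#'   unchanged.
#' @return a list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(nTfs = 30L, nGenes = 60L,
                          promoterLength = 1000L, motifWidth = 12L,
                          regulatorsPerGene = 3L, sitesPerEdge = 2L,
                          nPeripheralTfs = 2L,
                          trueKd = 1, perturbedTfs = numeric(),
                          repressorOnlyTfs = character(),
                          bodyLength = 1000L, bodyOpenFraction = 0.5,
                          noiseSigma = 0.05, refSteps = 40L,
                          params = modelParams(a = 10, kc = 1, d = 2.0,
                                               seThreshold = 4),
                          seed = 1L, noiseSeed = NULL) {
  if (nTfs > nGenes) stop("'nTfs' must not exceed 'nGenes'")
  if (motifWidth >= promoterLength)
    stop("motif longer than promoter")
  if (regulatorsPerGene >= nTfs)
    stop("'regulatorsPerGene' must be smaller than 'nTfs'")
  if (nPeripheralTfs >= nTfs - regulatorsPerGene)
    stop("'nPeripheralTfs' leaves too few connected factors")
  if (is.null(noiseSeed)) noiseSeed <- seed + 7919L
  structure(list(nTfs = as.integer(nTfs), nGenes = as.integer(nGenes),
                 promoterLength = as.integer(promoterLength),
                 motifWidth = as.integer(motifWidth),
                 regulatorsPerGene = as.integer(regulatorsPerGene),
                 sitesPerEdge = as.integer(sitesPerEdge),
                 nPeripheralTfs = as.integer(nPeripheralTfs),
                 trueKd = trueKd, perturbedTfs = perturbedTfs,
                 repressorOnlyTfs = repressorOnlyTfs,
                 bodyLength = as.integer(bodyLength),
                 bodyOpenFraction = bodyOpenFraction,
                 noiseSigma = noiseSigma, refSteps = as.integer(refSteps),
                 params = params, seed = as.integer(seed),
                 noiseSeed = as.integer(noiseSeed)),
            class = "FixtureConfig")
}

.randomSeq <- function(n) paste(sample(.BASES, n, TRUE), collapse = "")

.plantInto <- function(seq, at0, what) {
  # at0: 0-based offset
  paste0(substr(seq, 1L, at0), what,
         substr(seq, at0 + nchar(what) + 1L, nchar(seq)))
}

.revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

#' Generate a synthetic fixture bundle
#'
#' See [fixtureConfig()] for what is emulated. The bundle is
#' self-contained: running the region caller, the motif engine and the
#' forward model on it reproduces the recorded ground truth.
#'
#' @param config a [fixtureConfig()].
#' @param outDir optional directory; when given, all standard-format
#'   files (FASTA, GFF3, BEDs, JASPAR motifs, expression TSVs, annotation
#'   TSV plus `ground_truth/*.csv` and `config.json`) are written there.
#' @return a list of class `FixtureBundle` with elements `genome`,
#'   `genes`, `peaks`, `pfms`, `matrices`, `annotation`, `profiles`,
#'   `model`, `trueKd`, `xInit`, `xRef`, `xRefNoiseless`, `groundTruth`
#'   (planted-site table), `config` and, when written, `files`.
#' @export
generateFixture <- function(config = fixtureConfig(), outDir = NULL) {
  stopifnot(inherits(config, "FixtureConfig"))
  set.seed(config$seed)
  nT <- config$nTfs; nG <- config$nGenes
  wd <- config$motifWidth
  tfIds <- sprintf("TF%02d", seq_len(nT))
  geneIds <- c(tfIds, if (nG > nT) sprintf("GENE%02d", seq_len(nG - nT)))

  # distinct high-information motifs: planted consensus scores exactly 1
  repeat {
    consensus <- vapply(seq_len(nT),
                        function(i) .randomSeq(wd), "")
    if (!anyDuplicated(consensus)) break
  }
  pfms <- lapply(seq_len(nT), function(i) {
    m <- matrix(1, 4L, wd, dimnames = list(.BASES, NULL))
    hit <- match(strsplit(consensus[i], "")[[1L]], .BASES)
    m[cbind(hit, seq_len(wd))] <- 43
    m
  })
  names(pfms) <- tfIds
  matrices <- lapply(tfIds, function(id)
    pfmToScoreMatrix(pfms[[id]], id))
  names(matrices) <- tfIds

  # layout per gene (0-based, '+' strand): open promoter [100, 100+P),
  # TSS 100 bp before its end, gene body of bodyLength downstream
  P <- config$promoterLength
  promStart0 <- 100L
  promEnd0 <- promStart0 + P
  tss0 <- promEnd0 - 100L
  tes0 <- promEnd0 + config$bodyLength
  chromLen <- tes0 + 100L
  bodyOpen0 <- c(tss0 + 200L, tss0 + 400L)

  # deal regulators from repeated decks, factor genes first: every
  # factor gets a balanced number of factor-gene targets. Each deck
  # cycle is an independent permutation so a factor's targets do NOT
  # share one fixed co-regulator set — identical regulator tuples across
  # targets would make the individual constants unidentifiable.
  k <- config$regulatorsPerGene
  peripheralTfs <- if (config$nPeripheralTfs > 0L)
    sort(sample(tfIds, config$nPeripheralTfs)) else character()
  connected <- setdiff(tfIds, peripheralTfs)
  nC <- length(connected)
  periGene <- geneIds %in% peripheralTfs
  nDealt <- sum(!periGene)
  nCycles <- ceiling(nDealt * k / nC)
  deck <- unlist(lapply(seq_len(nCycles), function(i) sample(connected)))
  regOf <- rep(list(character()), nG)
  names(regOf) <- geneIds
  slot <- 0L
  for (j in which(!periGene)) {
    regOf[[j]] <- deck[(slot * k + 1L):((slot + 1L) * k)]
    if (anyDuplicated(regOf[[j]]))  # de-duplicate at cycle boundaries
      regOf[[j]] <- sample(connected, k)
    slot <- slot + 1L
  }

  hasBody <- stats::setNames(rep(FALSE, nG), geneIds)
  nBody <- round(config$bodyOpenFraction * nT)
  if (nBody > 0)
    hasBody[sample(tfIds, nBody)] <- TRUE

  # candidate non-overlapping plant slots inside the open promoter
  slotStep <- wd + 6L
  nSlots <- (P - 20L) %/% slotStep
  slots0 <- promStart0 + 10L + (seq_len(nSlots) - 1L) * slotStep

  seqs <- character(nG)
  gt <- list()
  for (j in seq_len(nG)) {
    gid <- geneIds[j]
    s <- .randomSeq(chromLen)
    need <- length(regOf[[j]]) * config$sitesPerEdge
    at <- if (need) sort(sample(slots0, need)) else integer()
    tf <- rep(regOf[[j]], each = config$sitesPerEdge)
    strand <- if (need)
      sample(c("+", "-"), need, TRUE, prob = c(0.75, 0.25))
    else character()
    for (i in seq_len(need)) {
      motif <- consensus[match(tf[i], tfIds)]
      if (strand[i] == "-") motif <- .revcomp(motif)
      s <- .plantInto(s, at[i], motif)
    }
    gtj <- data.frame(gene_id = rep(gid, need), tf_id = tf,
                      region = rep("promoter", need), offset = at,
                      strand = strand, stringsAsFactors = FALSE)
    if (hasBody[gid]) {
      btf <- sample(tfIds, 1L)
      bat <- bodyOpen0[1L] + 20L
      s <- .plantInto(s, bat, consensus[match(btf, tfIds)])
      gtj <- rbind(gtj, data.frame(gene_id = gid, tf_id = btf,
                                   region = "gene_body", offset = bat,
                                   strand = "+",
                                   stringsAsFactors = FALSE))
    }
    seqs[j] <- s
    gt[[j]] <- gtj
  }
  groundTruth <- do.call(rbind, gt)
  genome <- DNAStringSet(seqs)
  names(genome) <- paste0("chr_", geneIds)

  genes <- GRanges(paste0("chr_", geneIds),
                   IRanges(tss0 + 1L, tes0), strand = "+",
                   gene_id = geneIds)

  peakRows <- list()
  for (j in seq_len(nG)) {
    chr <- paste0("chr_", geneIds[j])
    # two overlapping histone peaks spanning the promoter, accessibility
    # in the middle: exercises cross-assay merging
    mid <- promStart0 + P %/% 2L
    peakRows[[j]] <- data.frame(
      chrom = chr,
      start = c(promStart0, mid - 50L, promStart0 + 200L,
                if (hasBody[geneIds[j]]) bodyOpen0[1L]),
      end = c(mid + 50L, promEnd0, promStart0 + 700L,
              if (hasBody[geneIds[j]]) bodyOpen0[2L]),
      assay = c("histone_chip", "histone_chip", "atac",
                if (hasBody[geneIds[j]]) "atac"),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peakRows)

  xSeed <- stats::setNames(stats::rlnorm(nG, log(1.5), 0.4), geneIds)

  trueKd <- stats::setNames(rep(config$trueKd, length.out = nT), tfIds)
  if (length(config$perturbedTfs)) {
    bad <- setdiff(names(config$perturbedTfs), tfIds)
    if (length(bad))
      stop("unknown perturbed tf_id: ", paste(bad, collapse = ", "))
  }
  kdRef <- trueKd
  kdRef[names(config$perturbedTfs)] <-
    kdRef[names(config$perturbedTfs)] * config$perturbedTfs

  openRegions <- callOpenRegions(peaks)
  annotation <- classifyRegions(openRegions, genes)
  mkModel <- function(prof) {
    trnModel(prof$promoterSites, prof$geneBodySites,
             roster = intersect(tfIds, names(annotation@promoters)),
             repressorOnly = config$repressorOnlyTfs,
             params = config$params)
  }
  # The initial expression table emulates a homeostatic snapshot: the
  # network's own unperturbed fixed point, observed with measurement
  # noise. Repressor selection uses that initial table, which only
  # exists after equilibrating, so equilibrate on repressor-free
  # profiles first; the weak competitive terms move the fixed point by
  # far less than the measurement noise.
  scanned <- .profileScan(annotation, genome, matrices, config$params)
  ki1 <- stats::setNames(rep(1, nT), tfIds)
  prof1 <- .assembleProfiles(scanned, xSeed[tfIds], ki1, config$params,
                             selectRepressors = FALSE)
  cm1 <- compileTRN(mkModel(prof1))
  xEq1 <- forwardSimulate(cm1, xSeed[cm1$roster], trueKd[cm1$roster],
                          config$refSteps, ki = trueKd[cm1$roster])
  xInit <- xSeed
  xInit[names(xEq1)] <- xEq1 *
    exp(stats::rnorm(length(xEq1), 0, config$noiseSigma))
  profiles <- .assembleProfiles(scanned, xInit[tfIds], ki1,
                                config$params)
  model <- mkModel(profiles)
  cm <- compileTRN(model)
  xEq <- forwardSimulate(cm, xEq1[cm$roster], trueKd[cm$roster],
                         config$refSteps, ki = trueKd[cm$roster])
  # the condition perturbs activator binding; competitor constants stay
  # at the unperturbed truth
  xFix <- forwardSimulate(cm, xEq, kdRef[cm$roster], config$refSteps,
                          ki = trueKd[cm$roster])
  set.seed(config$noiseSeed)
  noise <- exp(stats::rnorm(length(xFix), 0, config$noiseSigma))
  xRef <- xInit
  xRef[names(xFix)] <- xFix * noise

  bundle <- structure(list(
    genome = genome, genes = genes, peaks = peaks, pfms = pfms,
    matrices = matrices, openRegions = openRegions,
    annotation = annotation, profiles = profiles, model = model,
    trueKd = trueKd, refKd = kdRef, xInit = xInit, xEq = xEq,
    xRef = xRef, xRefNoiseless = xFix, groundTruth = groundTruth,
    peripheralTfs = peripheralTfs, connectedTfs = connected,
    config = config), class = "FixtureBundle")
  if (!is.null(outDir))
    bundle$files <- writeFixture(bundle, outDir)
  bundle
}

#' Regenerate a fixture's reference state under new perturbations
#'
#' Re-runs the forward model under the true dissociation constants with
#' the given fold changes applied and fresh noise; the structural ground
#' truth (genome, plants, tables) is untouched, so bundles differing only
#' in `seed` here have identical ground-truth tables.
#'
#' @param bundle a `FixtureBundle`.
#' @param tfFoldChanges named numeric of Kd fold changes (may be empty).
#' @param seed noise seed (defaults to the bundle's noise seed).
#' @return the bundle with updated `xRef`, `xRefNoiseless`, `refKd`.
#' @export
perturbReference <- function(bundle, tfFoldChanges = numeric(),
                             seed = NULL) {
  stopifnot(inherits(bundle, "FixtureBundle"))
  bad <- setdiff(names(tfFoldChanges), names(bundle$trueKd))
  if (length(bad))
    stop("unknown tf_id: ", paste(bad, collapse = ", "))
  if (is.null(seed)) seed <- bundle$config$noiseSeed
  kd <- bundle$trueKd
  kd[names(tfFoldChanges)] <- kd[names(tfFoldChanges)] * tfFoldChanges
  cm <- compileTRN(bundle$model)
  xFix <- forwardSimulate(cm, bundle$xEq, kd[cm$roster],
                          bundle$config$refSteps,
                          ki = bundle$trueKd[cm$roster])
  set.seed(seed)
  noise <- exp(stats::rnorm(length(xFix), 0, bundle$config$noiseSigma))
  bundle$xRef[names(xFix)] <- xFix * noise
  bundle$xRefNoiseless <- xFix
  bundle$refKd <- kd
  bundle$config$perturbedTfs <- tfFoldChanges
  bundle
}

#' Write a fixture bundle to standard-format files
#'
#' @param bundle a `FixtureBundle`.
#' @param dir output directory (created).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gtDir <- file.path(dir, "ground_truth")
  dir.create(gtDir, showWarnings = FALSE)
  f <- c(genome = file.path(dir, "genome.fa"),
         genes = file.path(dir, "genes.gff3"),
         histone = file.path(dir, "peaks_histone.bed"),
         atac = file.path(dir, "peaks_atac.bed"),
         motifs = file.path(dir, "motifs.jaspar"),
         exprInit = file.path(dir, "expr_initial.tsv"),
         exprRef = file.path(dir, "expr_reference.tsv"),
         tfAnnotation = file.path(dir, "tf_annotation.tsv"),
         sites = file.path(gtDir, "planted_sites.csv"),
         trueKd = file.path(gtDir, "true_kd.csv"),
         perturbed = file.path(gtDir, "perturbed_tfs.csv"),
         config = file.path(dir, "config.json"))
  writeXStringSet(bundle$genome, f["genome"], width = 80L)

  g <- bundle$genes
  gff <- g
  gff$source <- "trnscreen"
  gff$type <- "gene"
  gff$ID <- g$gene_id
  rtracklayer::export(gff, f["genes"], format = "gff3")

  pk <- bundle$peaks
  for (set in list(c("histone_chip", "histone"), c("atac", "atac"))) {
    sub <- pk[pk$assay == set[1L], , drop = FALSE]
    gr <- GRanges(sub$chrom, IRanges(sub$start + 1L, sub$end))
    rtracklayer::export(gr, f[set[2L]], format = "bed")
  }

  writeJasparMatrices(bundle$pfms, f["motifs"])
  writeExpression(bundle$xInit, f["exprInit"])
  writeExpression(bundle$xRef, f["exprRef"])

  tfIds <- names(bundle$trueKd)
  ro <- bundle$model@repressorOnly[tfIds]
  utils::write.table(
    data.frame(tf_id = tfIds, is_repressor_only = as.integer(ro)),
    f["tfAnnotation"], sep = "\t", quote = FALSE, row.names = FALSE)

  utils::write.csv(bundle$groundTruth, f["sites"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(tf_id = tfIds,
                              true_kd = unname(bundle$trueKd),
                              reference_kd = unname(bundle$refKd),
                              is_peripheral =
                                as.integer(tfIds %in%
                                           bundle$peripheralTfs)),
                   f["trueKd"], row.names = FALSE, quote = FALSE)
  pert <- bundle$config$perturbedTfs
  utils::write.csv(data.frame(tf_id = names(pert),
                              fold_change = unname(pert)),
                   f["perturbed"], row.names = FALSE, quote = FALSE)
  cfg <- bundle$config
  cfg$params <- list(a = cfg$params@a, kc = cfg$params@kc,
                     d = cfg$params@d,
                     seThreshold = cfg$params@seThreshold,
                     scoreFloor = cfg$params@scoreFloor)
  jsonlite::write_json(unclass(cfg), f["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(f)
}

#' Write / read a two-column expression table
#'
#' Tab-separated `gene_id` / `expression`, full precision, fixed order.
#'
#' @param x named numeric.
#' @param path TSV path.
#' @return `writeExpression()` returns `path` invisibly;
#'   `readExpression()` a named numeric vector.
#' @export
writeExpression <- function(x, path) {
  utils::write.table(
    data.frame(gene_id = names(x),
               expression = sprintf("%.17g", unname(x))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExpression
#' @export
readExpression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  stats::setNames(df[[2L]], df[[1L]])
}
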