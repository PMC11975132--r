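#' @include AllClasses.R regions.R motifs.R fit.R coretf.R
NULL

.pkgVersion <- function() {
  as.character(utils::packageVersion("trnscreen"))
}

.writeManifest <- function(dir, inputs, config, seed = NULL) {
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  hashes <- lapply(inputs, function(p) {
    if (is.character(p) && all(file.exists(p)))
      unname(tools::md5sum(p)) else NULL
  })
  jsonlite::write_json(
    list(package = "trnscreen", version = .pkgVersion(),
         inputs = inputs, input_md5 = hashes, config = config,
         seed = seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(file.path(dir, "manifest.json"))
}

#' Pipeline stage: call and classify open regions
#'
#' Reads per-assay peak BEDs and gene models, calls open-chromatin
#' regions, classifies them per gene and writes `open_regions.bed`,
#' `region_annotation.tsv` and a run manifest.
#'
#' @param gff gene models (GTF/GFF3 path).
#' @param histone,dnase,atac BED paths per assay; at least one
#'   accessibility file (dnase/atac) is required.
#' @param outDir output directory.
#' @return the [RegionAnnotation-class], invisibly.
#' @export
runRegionsStage <- function(gff, histone = character(),
                            dnase = character(), atac = character(),
                            outDir) {
  peaks <- readPeakBeds(histone, dnase, atac)
  genes <- readGeneModels(gff)
  open <- callOpenRegions(peaks)
  ann <- classifyRegions(open, genes)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rtracklayer::export(open, file.path(outDir, "open_regions.bed"),
                      format = "bed")
  writeRegionAnnotation(ann, file.path(outDir, "region_annotation.tsv"))
  .writeManifest(outDir,
                 list(gff = gff, histone = histone, dnase = dnase,
                      atac = atac),
                 list(stage = "regions"))
  invisible(ann)
}

#' Pipeline stage: build binding profiles
#'
#' Scans promoters and gene bodies with the motif roster and writes
#' `promoter_sites.csv`, `gene_body_sites.csv` and `roster.txt`. The
#' roster is the set of factors that have a motif and whose own gene has
#' an open promoter; genes present in the expression table but absent
#' from the annotation are logged and skipped.
#'
#' @param regionsDir output directory of [runRegionsStage()].
#' @param gff gene models used for that stage.
#' @param genomeFa genome FASTA path.
#' @param jaspar motif file (JASPAR text).
#' @param exprInit initial-state expression TSV.
#' @param params a [ModelParams-class].
#' @param outDir output directory.
#' @return list with `profiles`, `roster`, `matrices`, invisibly.
#' @export
runBindStage <- function(regionsDir, gff, genomeFa, jaspar, exprInit,
                         params = modelParams(), outDir) {
  genes <- readGeneModels(gff)
  ann <- readRegionAnnotation(
    file.path(regionsDir, "region_annotation.tsv"), genes)
  matrices <- readJasparMatrices(jaspar)
  expr <- readExpression(exprInit)
  missing <- setdiff(names(matrices), names(expr))
  if (length(missing))
    stop("expression missing for factors: ",
         paste(missing, collapse = ", "))
  orphans <- setdiff(names(expr), genes$gene_id)
  if (length(orphans))
    message(length(orphans),
            " expression record(s) without gene annotation skipped: ",
            paste(utils::head(orphans, 5L), collapse = ", "))
  prof <- buildBindingProfiles(ann, genomeFa, matrices,
                               expr[names(matrices)], params = params)
  rosterTfs <- intersect(names(matrices), names(ann@promoters))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeBindingSites(prof$promoterSites,
                    file.path(outDir, "promoter_sites.csv"))
  writeBindingSites(prof$geneBodySites,
                    file.path(outDir, "gene_body_sites.csv"))
  writeLines(rosterTfs, file.path(outDir, "roster.txt"))
  .writeManifest(outDir,
                 list(regions = file.path(regionsDir,
                                          "region_annotation.tsv"),
                      genome = genomeFa, jaspar = jaspar,
                      exprInit = exprInit),
                 list(stage = "bind", a = params@a,
                      scoreFloor = params@scoreFloor))
  invisible(list(profiles = prof, roster = rosterTfs,
                 matrices = matrices))
}

#' Pipeline stage: fit dissociation constants
#'
#' Builds the network model from a bind-stage directory, fits Kd by
#' gradient descent from the initial toward the reference expression
#' state and writes `kd_trajectory.csv`, `loss.csv`, `Act_list.csv`,
#' `Rep_list.csv` and `fit.json` (config echo and final Kd).
#'
#' @param bindDir output directory of [runBindStage()].
#' @param exprInit,exprRef expression TSVs (initial and reference
#'   states). Passing the initial table twice runs the self-referential
#'   control.
#' @param tfAnnotation optional TSV (`tf_id`, `is_repressor_only`).
#' @param params a [ModelParams-class].
#' @param config a [fitConfig()].
#' @param fixed named numeric of clamped Kd values (continuous
#'   activation/inhibition perturbations, e.g. `c(TF01 = 100)`).
#' @param referenceMode `"data"` uses `exprRef`; `"random"` replaces the
#'   reference by seeded uniform noise on its range and `"constant"` by
#'   its mean (robustness controls for the core set).
#' @param outDir output directory.
#' @return the [TRNFit-class], invisibly.
#' @export
runFitStage <- function(bindDir, exprInit, exprRef,
                        tfAnnotation = NULL, params = modelParams(),
                        config = fitConfig(), fixed = NULL,
                        referenceMode = c("data", "random", "constant"),
                        outDir) {
  referenceMode <- match.arg(referenceMode)
  for (f in c(file.path(bindDir, "promoter_sites.csv"),
              file.path(bindDir, "roster.txt"), exprInit, exprRef))
    if (!file.exists(f))
      stop("missing upstream file: ", f,
           " (run the bind stage first or check paths)")
  prom <- readBindingSites(file.path(bindDir, "promoter_sites.csv"))
  body <- readBindingSites(file.path(bindDir, "gene_body_sites.csv"))
  rosterTfs <- readLines(file.path(bindDir, "roster.txt"))
  xi <- readExpression(exprInit)
  xr <- readExpression(exprRef)
  repOnly <- character()
  if (!is.null(tfAnnotation)) {
    ta <- utils::read.table(tfAnnotation, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer"))
    repOnly <- ta$tf_id[ta$is_repressor_only == 1L]
    repOnly <- intersect(repOnly, rosterTfs)
  }
  model <- trnModel(prom, body, roster = rosterTfs,
                    repressorOnly = repOnly, params = params)
  miss <- setdiff(rosterTfs, names(xi))
  if (length(miss))
    stop("initial expression missing for: ",
         paste(miss, collapse = ", "))
  xr <- switch(referenceMode,
    data = xr,
    random = {
      if (!is.null(config$seed)) set.seed(config$seed)
      setNames(runif(length(rosterTfs), 0, max(xi[rosterTfs])),
               rosterTfs)
    },
    constant = setNames(rep(mean(xi[rosterTfs]), length(rosterTfs)),
                        rosterTfs))
  fit <- fitKd(model, xi[rosterTfs], xr[rosterTfs], config, fixed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  traj <- kdTrajectory(fit)
  trajDf <- data.frame(step = seq_len(nrow(traj)) - 1L,
                       apply(traj, 2L, function(x) sprintf("%.15g", x)),
                       check.names = FALSE)
  utils::write.csv(trajDf, file.path(outDir, "kd_trajectory.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(step = seq_along(lossTrajectory(fit)) - 1L,
                              loss = sprintf("%.15g",
                                             lossTrajectory(fit))),
                   file.path(outDir, "loss.csv"), row.names = FALSE,
                   quote = FALSE)
  dg <- digraphExport(actMatrix(fit), repMatrix(fit), dir = outDir)
  jsonlite::write_json(
    list(config = fit@config, referenceMode = referenceMode,
         kd_final = as.list(kdFinal(fit)),
         fixed = as.list(fit@config$fixed),
         roster = rosterTfs),
    file.path(outDir, "fit.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  .writeManifest(outDir,
                 list(bind = file.path(bindDir, "promoter_sites.csv"),
                      exprInit = exprInit, exprRef = exprRef,
                      tfAnnotation = tfAnnotation),
                 list(stage = "fit", nSteps = config$nSteps,
                      learningRate = config$learningRate,
                      innerIterations = config$innerIterations,
                      kdInit = config$kdInit,
                      referenceMode = referenceMode, a = params@a,
                      d = params@d),
                 seed = config$seed)
  invisible(fit)
}

# rebuild a TRNFit (trajectory + derivative matrices) from a fit
# directory written by runFitStage
.readFitDir <- function(dir) {
  traj <- utils::read.csv(file.path(dir, "kd_trajectory.csv"),
                          check.names = FALSE)
  step <- traj$step
  traj <- as.matrix(traj[, -1L, drop = FALSE])
  loss <- utils::read.csv(file.path(dir, "loss.csv"))$loss
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  roster <- colnames(traj)
  fixedNames <- names(meta$fixed)
  mask <- setNames(roster %in% fixedNames, roster)
  act <- readEdgeList(file.path(dir, "Act_list.csv"))
  rep_ <- readEdgeList(file.path(dir, "Rep_list.csv"))
  toMat <- function(e) {
    M <- matrix(0, length(roster), length(roster),
                dimnames = list(roster, roster))
    if (nrow(e)) M[cbind(e$source, e$target)] <- e$weight
    M
  }
  new("TRNFit", kdTrajectory = traj,
      kdFinal = setNames(traj[nrow(traj), ], roster),
      lossTrajectory = loss, AMatrix = toMat(act), RMatrix = toMat(rep_),
      fixedMask = mask,
      config = c(meta$config, list(fixed = unlist(meta$fixed))))
}

#' Pipeline stage: core-factor report and digraphs
#'
#' Reads a fit directory, writes `core_tfs.csv`, `report.json` and the
#' digraph files (absolute mode); with a control fit directory it also
#' writes the condition/control Kd-ratio table (`kd_ratio.csv`) and
#' ratio-mode digraphs under `ratio/`.
#'
#' @param fitDir output directory of [runFitStage()].
#' @param controlDir optional control fit directory (same roster).
#' @param tolerance core-factor threshold on `|log10(kd change)|`.
#' @param outDir output directory.
#' @return list with `core`, and `ratio` when a control is given,
#'   invisibly.
#' @export
runReportStage <- function(fitDir, controlDir = NULL, tolerance = 0.5,
                           outDir) {
  fit <- .readFitDir(fitDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  core <- coreTFs(fit, tolerance)
  utils::write.csv(core, file.path(outDir, "core_tfs.csv"),
                   row.names = FALSE, quote = FALSE)
  dg <- digraphExport(actMatrix(fit), repMatrix(fit), dir = outDir)
  out <- list(core = core)
  report <- list(tolerance = tolerance, n_core = nrow(core),
                 core_tfs = core$tf_id,
                 clamped = names(which(fixedMask(fit))))
  if (!is.null(controlDir)) {
    ctrl <- .readFitDir(controlDir)
    ratio <- kdRatioReport(fit, ctrl)
    utils::write.csv(
      transform(ratio$table,
                ratio = sprintf("%.15g", ratio),
                log2_ratio = sprintf("%.15g", log2_ratio)),
      file.path(outDir, "kd_ratio.csv"), row.names = FALSE,
      quote = FALSE)
    digraphExport(actMatrix(fit), repMatrix(fit),
                  mode = "condition_over_control",
                  controlA = actMatrix(ctrl), controlR = repMatrix(ctrl),
                  dir = file.path(outDir, "ratio"))
    report$most_inhibited <- ratio$mostInhibited
    report$most_activated <- ratio$mostActivated
    out$ratio <- ratio
  }
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  .writeManifest(outDir, list(fit = file.path(fitDir, "fit.json"),
                              control = if (!is.null(controlDir))
                                file.path(controlDir, "fit.json")),
                 list(stage = "report", tolerance = tolerance))
  invisible(out)
}

#' Run the full pipeline on one input set
#'
#' Convenience wrapper chaining the regions, bind, fit and report stages
#' into subdirectories of `outDir`.
#'
#' @inheritParams runRegionsStage
#' @inheritParams runBindStage
#' @inheritParams runFitStage
#' @param tolerance core-factor threshold.
#' @return list with the annotation, fit and report results, invisibly.
#' @export
runPipeline <- function(gff, genomeFa, jaspar, exprInit, exprRef,
                        histone = character(), dnase = character(),
                        atac = character(), tfAnnotation = NULL,
                        params = modelParams(), config = fitConfig(),
                        fixed = NULL, tolerance = 0.5, outDir) {
  ann <- runRegionsStage(gff, histone, dnase, atac,
                         outDir = file.path(outDir, "regions"))
  bind <- runBindStage(file.path(outDir, "regions"), gff, genomeFa,
                       jaspar, exprInit, params,
                       outDir = file.path(outDir, "bind"))
  fit <- runFitStage(file.path(outDir, "bind"), exprInit, exprRef,
                     tfAnnotation, params, config, fixed,
                     outDir = file.path(outDir, "fit"))
  rep_ <- runReportStage(file.path(outDir, "fit"),
                         tolerance = tolerance,
                         outDir = file.path(outDir, "report"))
  invisible(list(annotation = ann, bind = bind, fit = fit,
                 report = rep_))
}
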