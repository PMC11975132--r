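#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Normalised motif score matrix
#'
#' A per-position, per-base scoring model for one transcription factor,
#' min-max normalised over windows so that the consensus window scores
#' exactly 1 and the worst possible window scores exactly 0. The score of a
#' DNA window is the sum of the per-position weights of its bases, and
#' therefore always lies in \[0, 1\] (the binding score, Sp when the factor
#' acts as an activator, Sq when it competes as a repressor).
#'
#' @slot tfId single identifier of the factor.
#' @slot weights numeric matrix with rows A, C, G, T and one column per
#'   motif position; every column minimum is 0 and the column maxima sum
#'   to 1.
#'
#' @seealso [pfmToScoreMatrix()], [scanRegion()]
#' @export
setClass("ScoreMatrix",
  representation(tfId = "character", weights = "matrix"))

setValidity("ScoreMatrix", function(object) {
  w <- object@weights
  msg <- character()
  if (length(object@tfId) != 1L || is.na(object@tfId) || !nzchar(object@tfId))
    msg <- c(msg, "'tfId' must be a single non-empty string")
  if (!is.numeric(w) || nrow(w) != 4L || ncol(w) < 1L)
    msg <- c(msg, "'weights' must be a numeric 4 x width matrix")
  else {
    if (!identical(rownames(w), c("A", "C", "G", "T")))
      msg <- c(msg, "'weights' rows must be named A, C, G, T")
    if (any(!is.finite(w)))
      msg <- c(msg, "'weights' must be finite")
    else {
      if (max(abs(apply(w, 2L, min))) > 1e-9)
        msg <- c(msg, "each position's minimum weight must be 0")
      if (abs(sum(apply(w, 2L, max)) - 1) > 1e-9)
        msg <- c(msg, "position maxima must sum to 1 (consensus score 1)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Global parameters of the thermodynamic transcription model
#'
#' @slot a score weighting exponent: a site with score Sp contributes with
#'   weight 10^(-a(1-Sp)), so larger `a` makes binding increasingly
#'   consensus-specific (dimensionless, > 0).
#' @slot kc basal transcription constant; the activation flux from one
#'   factor saturates at `kc` (expression units per step, > 0).
#' @slot d degradation rate of the Michaelis-Menten decay
#'   dx/dt = -d x / (1 + x) applied over one step (dimensionless, >= 0).
#' @slot seThreshold super-enhancer trigger: when the summed top-4 site
#'   scores of one factor on one region exceed this, occupancy switches to
#'   the cooperative (Hill-type) form.
#' @slot pMax maximum number of binding sites retained per factor and
#'   region; fixed at 4.
#' @slot scoreFloor sites with Sp below this are not listed in binding
#'   profiles.
#'
#' @seealso [modelParams()]
#' @export
setClass("ModelParams",
  representation(a = "numeric", kc = "numeric", d = "numeric",
                 seThreshold = "numeric", pMax = "integer",
                 scoreFloor = "numeric"),
  prototype(a = 10, kc = 1, d = 1.5, seThreshold = 3, pMax = 4L,
            scoreFloor = 0.5))

setValidity("ModelParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@a) || object@a <= 0) msg <- c(msg, "'a' must be > 0")
  if (!one(object@kc) || object@kc <= 0) msg <- c(msg, "'kc' must be > 0")
  if (!one(object@d) || object@d < 0) msg <- c(msg, "'d' must be >= 0")
  if (!one(object@seThreshold)) msg <- c(msg, "'seThreshold' must be finite")
  if (!identical(object@pMax, 4L)) msg <- c(msg, "'pMax' must be 4")
  if (!one(object@scoreFloor) || object@scoreFloor < 0 ||
      object@scoreFloor > 1)
    msg <- c(msg, "'scoreFloor' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param a,kc,d,seThreshold,scoreFloor see [ModelParams-class].
#' @return a validated [ModelParams-class] object.
#' @examples
#' modelParams(a = 10, kc = 1, d = 1.5)
#' @export
modelParams <- function(a = 10, kc = 1, d = 1.5, seThreshold = 3,
                        scoreFloor = 0.5) {
  new("ModelParams", a = as.numeric(a), kc = as.numeric(kc),
      d = as.numeric(d), seThreshold = as.numeric(seThreshold),
      pMax = 4L, scoreFloor = as.numeric(scoreFloor))
}

.SITE_COLS <- c("gene_id", "tf_id", "site_rank", "offset", "strand",
                "sp", "repressor_id", "sq")

.checkSiteFrame <- function(df, what) {
  msg <- character()
  if (!is.data.frame(df))
    return(sprintf("'%s' must be a data.frame", what))
  miss <- setdiff(.SITE_COLS, names(df))
  if (length(miss))
    return(sprintf("'%s' lacks columns: %s", what,
                   paste(miss, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$site_rank < 1L | df$site_rank > 4L))
      msg <- c(msg, sprintf("'%s': site_rank must be in 1..4", what))
    if (any(df$sp < 0 | df$sp > 1))
      msg <- c(msg, sprintf("'%s': sp must be in [0, 1]", what))
    if (any(!is.na(df$sq) & (df$sq < 0 | df$sq > 1)))
      msg <- c(msg, sprintf("'%s': sq must be in [0, 1]", what))
    if (!all(df$strand %in% c("+", "-")))
      msg <- c(msg, sprintf("'%s': strand must be '+' or '-'", what))
  }
  msg
}

#' Transcription factor regulatory network model
#'
#' Container for a fully specified network: the factor roster (state vector
#' ordering), promoter and gene-body binding profiles, repressor-only
#' annotation flags, optional explicit inhibition constants, and the global
#' model parameters. Binding-site tables use the on-disk CSV column layout
#' (`gene_id, tf_id, site_rank, offset, strand, sp, repressor_id, sq`);
#' offsets are genomic 0-based starts.
#'
#' @slot roster character vector of factor ids; the state vector and the
#'   fitted dissociation constants are indexed by it.
#' @slot promoterSites data.frame of promoter binding sites.
#' @slot geneBodySites data.frame of gene-body binding sites.
#' @slot repressorOnly named logical, one entry per roster factor; `TRUE`
#'   flips the factor's promoter contribution to a subtracted term.
#' @slot ki named numeric of explicit inhibition constants, or empty to tie
#'   each factor's Ki to its current Kd (ratio 1).
#' @slot params a [ModelParams-class].
#'
#' @seealso [trnModel()], [trnStep()], [fitKd()]
#' @export
setClass("TRNModel",
  representation(roster = "character", promoterSites = "data.frame",
                 geneBodySites = "data.frame", repressorOnly = "logical",
                 ki = "numeric", params = "ModelParams"))

setValidity("TRNModel", function(object) {
  msg <- character()
  if (!length(object@roster))
    msg <- c(msg, "empty roster")
  if (anyDuplicated(object@roster))
    msg <- c(msg, "duplicated ids in roster")
  msg <- c(msg, .checkSiteFrame(object@promoterSites, "promoterSites"),
                .checkSiteFrame(object@geneBodySites, "geneBodySites"))
  for (df in list(object@promoterSites, object@geneBodySites)) {
    if (is.data.frame(df) && nrow(df) &&
        !all(df$tf_id %in% object@roster)) {
      msg <- c(msg, "binding-site tf_id outside the roster")
      break
    }
  }
  if (!identical(sort(names(object@repressorOnly)), sort(object@roster)))
    msg <- c(msg, "'repressorOnly' must be named by the full roster")
  if (length(object@ki)) {
    if (!all(names(object@ki) %in% object@roster) || any(object@ki <= 0))
      msg <- c(msg, "'ki' must be positive and named by roster factors")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a regulatory network model
#'
#' @param promoterSites,geneBodySites binding-site data.frames as produced
#'   by [buildBindingProfiles()] (gene-body table may be empty).
#' @param roster factor ids defining the state-vector order; defaults to
#'   the factors appearing in the promoter table.
#' @param repressorOnly character vector of factor ids annotated as
#'   repressor-only, or a named logical over the roster.
#' @param ki optional named numeric of explicit inhibition constants.
#' @param params a [ModelParams-class].
#' @return a validated [TRNModel-class].
#' @export
trnModel <- function(promoterSites, geneBodySites = NULL, roster = NULL,
                     repressorOnly = character(), ki = numeric(),
                     params = modelParams()) {
  if (is.null(geneBodySites))
    geneBodySites <- emptySiteFrame()
  if (is.null(roster))
    roster <- sort(unique(promoterSites$tf_id))
  if (is.character(repressorOnly)) {
    bad <- setdiff(repressorOnly, roster)
    if (length(bad))
      stop("repressor-only ids not in roster: ", paste(bad, collapse = ", "))
    repressorOnly <- stats::setNames(roster %in% repressorOnly, roster)
  }
  new("TRNModel", roster = roster,
      promoterSites = as.data.frame(promoterSites),
      geneBodySites = as.data.frame(geneBodySites),
      repressorOnly = repressorOnly, ki = ki, params = params)
}

#' Empty binding-site table
#'
#' @return a zero-row data.frame with the binding-site CSV columns.
#' @export
emptySiteFrame <- function() {
  data.frame(gene_id = character(), tf_id = character(),
             site_rank = integer(), offset = integer(),
             strand = character(), sp = numeric(),
             repressor_id = character(), sq = numeric(),
             stringsAsFactors = FALSE)
}

#' Result of a dissociation-constant fit
#'
#' @slot kdTrajectory numeric matrix, (steps + 1) x factors; row 1 is the
#'   initial Kd vector, later rows follow each descent step.
#' @slot kdFinal named numeric of fitted dissociation constants.
#' @slot lossTrajectory numeric, loss before each step plus the final loss.
#' @slot AMatrix,RMatrix derivative-factor matrices (regulator x target):
#'   sensitivities of each gene's promoter activation / gene-body
#'   repression term to each regulator's concentration, evaluated at the
#'   fitted optimum.
#' @slot fixedMask named logical; `TRUE` entries were clamped.
#' @slot config list echoing the fit configuration.
#'
#' @seealso [fitKd()], [coreTFs()], [digraphExport()]
#' @export
setClass("TRNFit",
  representation(kdTrajectory = "matrix", kdFinal = "numeric",
                 lossTrajectory = "numeric", AMatrix = "matrixOrNULL",
                 RMatrix = "matrixOrNULL", fixedMask = "logical",
                 config = "list"))

setValidity("TRNFit", function(object) {
  msg <- character()
  n <- length(object@kdFinal)
  if (ncol(object@kdTrajectory) != n)
    msg <- c(msg, "trajectory width must match roster size")
  if (any(!is.finite(object@lossTrajectory)))
    msg <- c(msg, "losses must be finite")
  if (any(object@kdFinal <= 0))
    msg <- c(msg, "fitted Kd values must be positive")
  if (!identical(names(object@fixedMask), names(object@kdFinal)))
    msg <- c(msg, "'fixedMask' names must match 'kdFinal'")
  if (length(msg)) msg else TRUE
})

#' Promoter / gene-body annotation of genes against open regions
#'
#' @slot genes `GRanges` of the annotated genes (metadata column
#'   `gene_id`), oriented so that the range runs from min to max of
#'   TSS/TES with the strand recording direction.
#' @slot promoters `GRanges` named by gene id: for each gene with an open
#'   promoter, the open region containing its transcription start site.
#' @slot geneBodies `GRangesList` named by gene id: open regions
#'   intersected with the TSS-to-TES span, promoter overlap removed.
#' @slot excluded character, ids of genes whose TSS lies in no open region
#'   (excluded from the network roster).
#'
#' @seealso [classifyRegions()]
#' @export
setClass("RegionAnnotation",
  representation(genes = "GRanges", promoters = "GRanges",
                 geneBodies = "GRangesList", excluded = "character"))

setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix for", object@tfId, "- width", ncol(object@weights),
      "- consensus", .scoreMatrixConsensus(object), "\n")
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(
    "ModelParams: a=%g kc=%g d=%g seThreshold=%g pMax=%d scoreFloor=%g\n",
    object@a, object@kc, object@d, object@seThreshold, object@pMax,
    object@scoreFloor))
})

setMethod("show", "TRNModel", function(object) {
  cat("TRNModel with", length(object@roster), "factors;",
      nrow(object@promoterSites), "promoter sites,",
      nrow(object@geneBodySites), "gene-body sites;",
      sum(object@repressorOnly), "repressor-only\n")
})

setMethod("show", "TRNFit", function(object) {
  cat("TRNFit:", length(object@kdFinal), "factors,",
      nrow(object@kdTrajectory) - 1L, "descent steps; final loss",
      format(utils::tail(object@lossTrajectory, 1L), digits = 6),
      "-", sum(object@fixedMask), "clamped\n")
})

setMethod("show", "RegionAnnotation", function(object) {
  cat("RegionAnnotation:", length(object@genes), "genes,",
      length(object@promoters), "with open promoters,",
      length(object@excluded), "excluded\n")
})
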