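#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname coreTFs
setMethod("coreTFs", "TRNFit", function(fit, tolerance = 0.5) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("'tolerance' must be a single non-negative number")
  kdInit <- fit@kdTrajectory[1L, ]
  change <- log10(fit@kdFinal / kdInit)
  keep <- !fit@fixedMask & abs(change) > tolerance
  out <- data.frame(tf_id = names(fit@kdFinal)[keep],
                    kd_init = unname(kdInit[keep]),
                    kd_final = unname(fit@kdFinal[keep]),
                    log10_change = unname(change[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log10_change), out$tf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Condition-versus-control dissociation-constant ratios
#'
#' Compares two fits sharing a roster and configuration but differing in
#' the reference expression state. Higher fitted Kd means weaker binding,
#' so the factor with the maximum ratio is the most inhibited in the
#' condition and the minimum ratio the most activated. Factors clamped in
#' either fit are flagged and excluded from the ranking.
#'
#' @param fitCondition,fitControl two [TRNFit-class] objects.
#' @return list with `table` (data.frame: `tf_id`, `kd_condition`,
#'   `kd_control`, `ratio`, `log2_ratio`, `clamped`), `mostInhibited`,
#'   `mostActivated` (factor ids among unclamped entries).
#' @export
kdRatioReport <- function(fitCondition, fitControl) {
  a <- names(fitCondition@kdFinal)
  b <- names(fitControl@kdFinal)
  if (!identical(sort(a), sort(b))) {
    diffs <- c(setdiff(a, b), setdiff(b, a))
    stop("roster mismatch between fits: ", paste(diffs, collapse = ", "))
  }
  kdC <- fitCondition@kdFinal
  kdK <- fitControl@kdFinal[a]
  clamped <- fitCondition@fixedMask | fitControl@fixedMask[a]
  ratio <- kdC / kdK
  tab <- data.frame(tf_id = a, kd_condition = unname(kdC),
                    kd_control = unname(kdK), ratio = unname(ratio),
                    log2_ratio = unname(log2(ratio)),
                    clamped = unname(clamped), stringsAsFactors = FALSE)
  tab <- tab[order(-tab$ratio), , drop = FALSE]
  rownames(tab) <- NULL
  open <- tab[!tab$clamped, , drop = FALSE]
  list(table = tab,
       mostInhibited = if (nrow(open)) open$tf_id[which.max(open$ratio)]
                       else NA_character_,
       mostActivated = if (nrow(open)) open$tf_id[which.min(open$ratio)]
                       else NA_character_)
}

.edgeFrame <- function(M, sign, mode, control = NULL, dropTol = 1e-12) {
  reg <- rownames(M); tgt <- colnames(M)
  idx <- which(M != 0, arr.ind = TRUE)
  w <- M[idx]
  src <- reg[idx[, 1L]]; dst <- tgt[idx[, 2L]]
  if (mode == "condition_over_control") {
    cw <- control[idx]
    keep <- abs(cw) > dropTol
    if (any(!keep))
      warning(sum(!keep), " ", sign,
              " edge(s) dropped: control weight below ", dropTol)
    src <- src[keep]; dst <- dst[keep]
    w <- w[keep] / cw[keep]
  }
  if (!length(w))
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), sign = character(),
                      mode = character(), stringsAsFactors = FALSE))
  df <- data.frame(source = src, target = dst, weight = w, sign = sign,
                   mode = mode, stringsAsFactors = FALSE)
  df[order(df$source, df$target), , drop = FALSE]
}

#' Export activator / repressor digraphs from derivative factors
#'
#' Builds regulator-to-target edge sets from the derivative-factor
#' matrices of a fit: one activating edge per nonzero promoter
#' sensitivity and one repressive edge per nonzero gene-body sensitivity.
#' In ratio mode each weight is divided by the matching control entry
#' (condition/control), dropping edges whose control weight is below
#' 1e-12. Nodes are ranked by in-degree: factors with more entering edges
#' sit more centrally in the network. Optionally writes `Act_list.csv`,
#' `Rep_list.csv` and a GraphML exchange file.
#'
#' @param A,R derivative-factor matrices (regulator x target), e.g. from
#'   [actMatrix()]/[repMatrix()].
#' @param mode `"absolute"` or `"condition_over_control"`.
#' @param controlA,controlR control matrices, required in ratio mode and
#'   shape-checked against `A`/`R`.
#' @param dir output directory; `NULL` skips file output.
#' @return list with `edges` (data.frame: source, target, weight, sign,
#'   mode), `graph` (an igraph digraph), `inDegree`, `outDegree` (sorted
#'   decreasing) and `files` (paths written, if any).
#' @export
digraphExport <- function(A, R, mode = c("absolute",
                                         "condition_over_control"),
                          controlA = NULL, controlR = NULL, dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "condition_over_control") {
    if (is.null(controlA) || is.null(controlR))
      stop("ratio mode needs 'controlA' and 'controlR'")
    if (!identical(dim(A), dim(controlA)) ||
        !identical(dim(R), dim(controlR)))
      stop("shape mismatch between condition and control matrices")
  }
  act <- .edgeFrame(A, "activating", mode, controlA)
  rep_ <- .edgeFrame(R, "repressive", mode, controlR)
  edges <- rbind(act, rep_)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(rownames(A), colnames(A))))
  g <- igraph::graph_from_data_frame(edges[, c("source", "target",
                                               "weight", "sign")],
                                     directed = TRUE,
                                     vertices = nodes)
  din <- sort(igraph::degree(g, mode = "in"), decreasing = TRUE)
  dout <- sort(igraph::degree(g, mode = "out"), decreasing = TRUE)
  files <- character()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    actPath <- file.path(dir, "Act_list.csv")
    repPath <- file.path(dir, "Rep_list.csv")
    gmlPath <- file.path(dir, "network.graphml")
    writeEdgeList(act, actPath)
    writeEdgeList(rep_, repPath)
    igraph::write_graph(g, gmlPath, format = "graphml")
    files <- c(Act_list = actPath, Rep_list = repPath, graphml = gmlPath)
  }
  list(edges = edges, graph = g, inDegree = din, outDegree = dout,
       files = files)
}

#' Write / read a digraph edge list CSV
#'
#' Deterministic full-precision CSV with columns `source`, `target`,
#' `weight`, `sign`, `mode`; `readEdgeList(writeEdgeList(x))`
#' round-trips.
#'
#' @param edges edge data.frame.
#' @param path CSV path.
#' @return `writeEdgeList()` returns `path` invisibly; `readEdgeList()`
#'   the data.frame.
#' @export
writeEdgeList <- function(edges, path) {
  df <- edges
  df$weight <- sprintf("%.17g", df$weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(source = "character",
                                 target = "character",
                                 weight = "numeric", sign = "character",
                                 mode = "character"))
}
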