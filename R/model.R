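#' @include AllClasses.R
NULL

# W0(e^z) for real z, vectorised and overflow-safe.
#
# Solves u + exp(u) = z by Newton in u = log w; the objective is convex
# and increasing, and the starting point u0 = log(z) (z > 1) or u0 = z
# (z <= 1) lies right of the root, so the iteration converges
# monotonically. Avoids forming exp(z), which overflows for
# expression-scale arguments.
.lambertW0exp <- function(z) {
  u <- z
  big <- z > 1
  u[big] <- log(z[big])
  for (i in 1:50) {
    eu <- exp(u)
    f <- u + eu - z
    du <- f / (1 + eu)
    u <- u - du
    if (max(abs(du)) < 1e-15) break
  }
  exp(u)
}

#' Residual concentration after one step of Michaelis-Menten degradation
#'
#' Closed-form one-step solution of dx/dt = -d x / (1 + x):
#' `g(x) = W(exp(x + log x - d))` with `W` the principal Lambert-W
#' branch. `g(0) = 0`, `g` is increasing in `x`, decreasing in `d`, and
#' `0 <= g(x) <= x` (identity at `d = 0`).
#'
#' @param x non-negative concentration(s).
#' @param d degradation rate, >= 0 (scalar or same length as `x`).
#' @return residual concentration(s) after one time unit.
#' @examples
#' degrade(1, 0)        # 1 (no degradation)
#' degrade(1, 1)        # W(1) ~ 0.567
#' @export
degrade <- function(x, d) {
  if (any(x < 0)) stop("'x' must be non-negative")
  if (any(d < 0)) stop("'d' must be non-negative")
  n <- max(length(x), length(d))
  x <- rep_len(x, n)
  d <- rep_len(d, n)
  out <- numeric(n)
  pos <- x > 0
  if (any(pos))
    out[pos] <- .lambertW0exp(x[pos] + log(x[pos]) - d[pos])
  out
}

#' Exponential site weight of a binding score
#'
#' A site with normalised score `sp` contributes with weight
#' `10^(-a (1 - sp))`: the consensus (sp = 1) gets weight 1 and weights
#' decay exponentially as the score drops, with steepness `a`.
#'
#' @param sp score(s) in \[0, 1\].
#' @param a weighting exponent, > 0.
#' @return weight(s) in (0, 1\].
#' @examples
#' siteWeight(1, 10)    # 1
#' siteWeight(0.9, 10)  # 0.1
#' @export
siteWeight <- function(sp, a) {
  if (any(sp < 0 | sp > 1)) stop("'sp' must lie in [0, 1]")
  if (any(a <= 0)) stop("'a' must be > 0")
  10^(-a * (1 - sp))
}

#' Expected occupancy of an activator across its binding sites
#'
#' Sub-threshold (sum of scores <= `seThreshold`), each site contributes
#' an independent competitive-equilibrium term
#' `w_p A / (Kd + w_p A + w_q (Kd/Ki) R)` with `w = 10^(-a(1-S))`; the
#' repressor term vanishes for sites without a competitor. Above the
#' threshold the sites act cooperatively (super-enhancer regime), a
#' Hill-type switch over the whole site group:
#' `r = P sum_j w_j A^j / (Kd^P + sum_j w_j A^j + sum_j w_qj (Kd/Ki_j) R_j)`
#' with `j` the site rank and `P` the number of sites, so a saturated
#' super enhancer reaches the same maximal occupancy `P` as `P`
#' saturated independent sites, but switches on nonlinearly. In both
#' regimes `0 <= r <=` number of sites, and both reduce to the same
#' expression for a single site.
#'
#' @param sp numeric vector (length <= 4) of site scores, descending.
#' @param A activator concentration, >= 0.
#' @param kd activator dissociation constant, > 0.
#' @param a weighting exponent.
#' @param sq per-site competitor scores (`NA` = no competitor).
#' @param repConc per-site competitor concentrations.
#' @param ki per-site competitor inhibition constants.
#' @param seThreshold super-enhancer trigger on `sum(sp)`.
#' @return the occupancy `r`.
#' @examples
#' occupancy(c(1, 1), A = 2, kd = 2, a = 10)  # 2 * A/(kd+A) = 1
#' @export
occupancy <- function(sp, A, kd, a, sq = NULL, repConc = NULL, ki = NULL,
                      seThreshold = 3) {
  p <- length(sp)
  if (p == 0L || A == 0) return(0)
  if (p > 4L) stop("at most 4 sites per factor and region")
  if (A < 0 || kd <= 0) stop("need A >= 0 and kd > 0")
  if (is.null(sq)) sq <- rep(NA_real_, p)
  if (is.null(repConc)) repConc <- rep(0, p)
  if (is.null(ki)) ki <- rep(1, p)
  wp <- siteWeight(sp, a)
  hasR <- !is.na(sq) & repConc > 0
  wq <- ifelse(hasR, siteWeight(ifelse(hasR, sq, 0), a), 0)
  repTerm <- ifelse(hasR, wq * (kd / ki) * repConc, 0)
  if (sum(sp) <= seThreshold) {
    sum(wp * A / (kd + wp * A + repTerm))
  } else {
    num <- sum(wp * A^seq_len(p))
    p * num / (kd^p + num + sum(repTerm))
  }
}

#' Activation flux from an occupancy
#'
#' The transcription flux contributed by one bound factor:
#' `kc * exp(-1/r)`, increasing in the occupancy `r`, saturating at `kc`,
#' and 0 at `r = 0` (continuous limit).
#'
#' @param r occupancy, >= 0.
#' @param kc basal transcription constant.
#' @return flux in \[0, kc).
#' @export
activatorContribution <- function(r, kc) {
  if (any(r < 0)) stop("'r' must be non-negative")
  ifelse(r > 0, kc * exp(-1 / r), 0)
}

# ---- compiled forward model ------------------------------------------------

# Compile one site table (promoter or gene body) into flat index vectors
# grouped by (gene, factor) for fast vectorised evaluation. Only rows
# whose target gene and factor are both on the roster enter the dynamics.
.compileSites <- function(sites, roster, params, repressorOnly,
                          bodySide = FALSE) {
  idx <- match(sites$gene_id, roster)
  tdx <- match(sites$tf_id, roster)
  keep <- !is.na(idx) & !is.na(tdx)
  sites <- sites[keep, , drop = FALSE]
  idx <- idx[keep]; tdx <- tdx[keep]
  if (!nrow(sites)) {
    return(list(n = 0L))
  }
  rdx <- match(sites$repressor_id, roster)
  rdx[is.na(rdx)] <- 0L
  ord <- order(idx, tdx, sites$site_rank)
  sites <- sites[ord, , drop = FALSE]
  idx <- idx[ord]; tdx <- tdx[ord]; rdx <- rdx[ord]
  grpKey <- idx * (length(roster) + 1L) + tdx
  grp <- cumsum(c(TRUE, diff(grpKey) != 0L))
  nG <- grp[length(grp)]
  first <- which(c(TRUE, diff(grpKey) != 0L))
  grpGene <- idx[first]
  grpTf <- tdx[first]
  grpSize <- tabulate(grp, nG)
  spSum <- as.vector(rowsum(sites$sp, grp, reorder = FALSE))
  se <- spSum > params@seThreshold
  wp <- siteWeight(sites$sp, params@a)
  wq <- ifelse(is.na(sites$sq), 0, siteWeight(ifelse(is.na(sites$sq),
                                                     0, sites$sq),
                                              params@a))
  rank <- sites$site_rank
  sign <- if (bodySide) rep(-1, nG) else
    ifelse(repressorOnly[roster[grpTf]], -1, 1)
  geneLevels <- sort(unique(grpGene))
  seRow <- se[grp]
  # groups (and genes over groups) are contiguous after the sort, so
  # group sums reduce to cumsum differences at the run ends
  grpEnds <- c(which(diff(grpKey) != 0L), length(grpKey))
  geneEnds <- c(which(diff(grpGene) != 0L), nG)
  list(n = nrow(sites), tIdx = tdx, rIdx = rdx, wp = wp, wq = wq,
       rank = rank, grp = grp, nGroups = nG, grpGene = grpGene,
       grpTf = grpTf, grpSize = grpSize, grpSE = se, grpSign = sign,
       hasRRows = which(rdx > 0L), subRows = which(!seRow),
       seRows = which(seRow), seGroups = which(se),
       grpEnds = grpEnds, geneEnds = geneEnds,
       geneLevels = geneLevels,
       geneMap = match(grpGene, geneLevels))
}

#' Compile a network model for fast simulation
#'
#' Precomputes flat index vectors from the binding-site tables; the
#' result is consumed by [trnStep()], [forwardSimulate()] and [fitKd()].
#' Compilation is deterministic and independent of input row order.
#'
#' @param model a [TRNModel-class].
#' @return an opaque list (class `CompiledTRN`).
#' @export
compileTRN <- function(model) {
  stopifnot(is(model, "TRNModel"))
  validObject(model)
  roster <- model@roster
  cm <- list(
    roster = roster,
    nT = length(roster),
    params = model@params,
    repressorOnly = model@repressorOnly[roster],
    kiFixed = if (length(model@ki))
      model@ki[roster] else NULL,
    prom = .compileSites(model@promoterSites, roster, model@params,
                         model@repressorOnly, bodySide = FALSE),
    body = .compileSites(model@geneBodySites, roster, model@params,
                         model@repressorOnly, bodySide = TRUE))
  class(cm) <- "CompiledTRN"
  cm
}

# per-gene summed signed flux from one compiled site set
.sideFlux <- function(cs, x, kd, ki, params) {
  out <- numeric(length(x))
  if (cs$n == 0L) return(out)
  A <- x[cs$tIdx]
  kdv <- kd[cs$tIdx]
  repTerm <- numeric(cs$n)
  hr <- cs$hasRRows
  if (length(hr))
    repTerm[hr] <- cs$wq[hr] * (kdv[hr] / ki[cs$rIdx[hr]]) * x[cs$rIdx[hr]]
  gsum <- function(v) diff(c(0, cumsum(v)[cs$grpEnds]))
  term <- numeric(cs$n)
  sub <- cs$subRows
  if (length(sub)) {
    wA <- cs$wp[sub] * A[sub]
    term[sub] <- wA / (kdv[sub] + wA + repTerm[sub])
  }
  r <- gsum(term)
  seR <- cs$seRows
  if (length(seR)) {
    num <- numeric(cs$n)
    num[seR] <- cs$wp[seR] * A[seR]^cs$rank[seR]
    numG <- gsum(num)
    seRowMask <- numeric(cs$n)
    seRowMask[seR] <- repTerm[seR]
    repG <- gsum(seRowMask)
    seG <- cs$seGroups
    den <- kd[cs$grpTf[seG]]^cs$grpSize[seG] + numG[seG] + repG[seG]
    rSe <- cs$grpSize[seG] * numG[seG] / den
    rSe[den <= 0] <- 0
    r[seG] <- rSe
  }
  flux <- numeric(cs$nGroups)
  pos <- r > 0
  flux[pos] <- params@kc * exp(-1 / r[pos])
  flux <- flux * cs$grpSign
  byGene <- diff(c(0, cumsum(flux)[cs$geneEnds]))
  out[cs$geneLevels] <- byGene
  out
}

# effective inhibition constants: explicit table when given, else tied
# to the current Kd (ratio 1)
.effKi <- function(cm, kd) {
  if (is.null(cm$kiFixed)) kd else cm$kiFixed
}

#' Gene-regulation flux of the whole network
#'
#' Computes, for every roster gene, the promoter-side flux (activators
#' summed, repressor-only factors subtracted) minus the gene-body-side
#' flux (all subtracted), clamped at zero to prevent negative regulation.
#'
#' @param cm a compiled model from [compileTRN()].
#' @param x named or roster-ordered concentration vector, >= 0.
#' @param kd roster-ordered dissociation constants, > 0.
#' @param ki optional roster-ordered inhibition constants; default ties
#'   Ki to Kd unless the model carries an explicit table.
#' @return list with `flux` (clamped per-gene regulation), `promoter` and
#'   `geneBody` (the two signed per-gene terms).
#' @export
geneRegulation <- function(cm, x, kd, ki = NULL) {
  stopifnot(inherits(cm, "CompiledTRN"))
  x <- .asState(cm, x)
  if (is.null(ki)) ki <- .effKi(cm, kd)
  prom <- .sideFlux(cm$prom, x, kd, ki, cm$params)
  body <- .sideFlux(cm$body, x, kd, ki, cm$params)
  flux <- prom + body  # body signs are already negative
  flux[flux < 0] <- 0
  list(flux = flux, promoter = prom, geneBody = body)
}

.asState <- function(cm, x) {
  if (!is.null(names(x))) {
    if (!all(cm$roster %in% names(x)))
      stop("state lacks entries for: ",
           paste(setdiff(cm$roster, names(x)), collapse = ", "))
    x <- x[cm$roster]
  } else if (length(x) != cm$nT) {
    stop("state length does not match roster")
  }
  if (any(x < 0)) stop("state must be non-negative")
  unname(x)
}

#' One step of the network state update
#'
#' `x_{n+1} = f(x_n) + g(x_n)`: the clamped gene-regulation flux plus the
#' Lambert-W Michaelis-Menten degradation residual. Non-negativity is
#' preserved for any parameters.
#'
#' @inheritParams geneRegulation
#' @return the next state, named by the roster.
#' @export
trnStep <- function(cm, x, kd, ki = NULL) {
  f <- geneRegulation(cm, x, kd, ki)$flux
  x <- .asState(cm, x)
  setNames(f + degrade(x, cm$params@d), cm$roster)
}

#' Iterate the forward model
#'
#' @inheritParams geneRegulation
#' @param nSteps number of update steps.
#' @param keepTrajectory return the full (nSteps + 1) x factors matrix
#'   instead of the final state.
#' @return final state (named numeric) or trajectory matrix.
#' @export
forwardSimulate <- function(cm, x, kd, nSteps, ki = NULL,
                            keepTrajectory = FALSE) {
  x <- .asState(cm, x)
  kd <- unname(kd)
  if (is.null(ki)) ki <- .effKi(cm, kd)
  p <- cm$params
  if (keepTrajectory) {
    tr <- matrix(NA_real_, nSteps + 1L, cm$nT,
                 dimnames = list(NULL, cm$roster))
    tr[1L, ] <- x
    for (s in seq_len(nSteps)) {
      x <- .stepFast(cm, x, kd, ki, p)
      tr[s + 1L, ] <- x
    }
    return(tr)
  }
  for (s in seq_len(nSteps)) x <- .stepFast(cm, x, kd, ki, p)
  setNames(x, cm$roster)
}

# unchecked hot path of trnStep
.stepFast <- function(cm, x, kd, ki, p) {
  f <- .sideFlux(cm$prom, x, kd, ki, p) +
    .sideFlux(cm$body, x, kd, ki, p)
  f[f < 0] <- 0
  f + degrade(x, p@d)
}
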