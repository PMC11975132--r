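#' @include AllClasses.R model.R
NULL

#' Fit configuration
#'
#' @param nSteps outer gradient-descent steps (default 20).
#' @param learningRate step size on log10-Kd (default 0.1).
#' @param innerIterations forward-model steps per loss evaluation. The
#'   default 30 lets the prediction reach the regulated steady state
#'   from a homeostatic initial snapshot, so a reference produced by the
#'   model class is reachable by the prediction map; much shorter
#'   horizons attribute downstream cascade changes to the cascaded
#'   factors' own constants.
#' @param fdStep central-finite-difference perturbation on log10-Kd.
#' @param kdInit initial dissociation constant, scalar or per-factor.
#' @param gradClip per-coordinate gradient clip on log10-Kd. Long
#'   prediction horizons make the loss extremely sensitive near
#'   occupancy switch points, where raw gradient entries overshoot by
#'   orders of magnitude; clipping keeps the descent direction while
#'   bounding per-factor movement.
#' @param lineSearchMax each descent step evaluates step lengths
#'   `learningRate * 2^k` for `k = lineSearchMax .. -2` along the
#'   clipped gradient and takes the best one satisfying the Armijo
#'   decrease condition, keeping the loss trajectory monotone.
#' @param seed echoed into results for provenance (the fit itself is
#'   deterministic).
#' @return a list of class `FitConfig`.
#' @export
fitConfig <- function(nSteps = 20L, learningRate = 0.1,
                      innerIterations = 30L, fdStep = 1e-4, kdInit = 1,
                      gradClip = 1, lineSearchMax = 4L, seed = NULL) {
  stopifnot(nSteps >= 1L, learningRate > 0, innerIterations >= 1L,
            fdStep > 0, all(kdInit > 0), gradClip > 0,
            lineSearchMax >= 0L)
  structure(list(nSteps = as.integer(nSteps),
                 learningRate = learningRate,
                 innerIterations = as.integer(innerIterations),
                 fdStep = fdStep, kdInit = kdInit, gradClip = gradClip,
                 lineSearchMax = as.integer(lineSearchMax),
                 seed = seed),
            class = "FitConfig")
}

#' Weighted squared-error loss between two expression states
#'
#' Squared error on `log1p` concentrations, weighted per factor. The
#' default weights are the reference concentrations normalised to mean 1,
#' so abundant reference factors dominate the objective.
#'
#' @param xPred,xRef roster-aligned non-negative vectors.
#' @param weights non-negative weights; `NULL` for the
#'   reference-proportional default. All-zero weights give loss 0 with a
#'   warning.
#' @return a scalar, 0 iff the states agree on positively weighted
#'   entries.
#' @export
trnLoss <- function(xPred, xRef, weights = NULL) {
  if (length(xPred) != length(xRef))
    stop("state lengths differ")
  if (is.null(weights)) {
    m <- mean(xRef)
    weights <- if (m > 0) xRef / m else rep(0, length(xRef))
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  if (all(weights == 0))
    warning("all loss weights are zero; loss is identically 0")
  sum(weights * (log1p(xPred) - log1p(xRef))^2)
}

.resolveFixed <- function(fixed, roster) {
  mask <- setNames(rep(FALSE, length(roster)), roster)
  vals <- setNames(rep(NA_real_, length(roster)), roster)
  if (length(fixed)) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed))))
      stop("'fixed' must be a named numeric (tf_id = clamped Kd)")
    bad <- setdiff(names(fixed), roster)
    if (length(bad))
      stop("clamped ids not in roster: ", paste(bad, collapse = ", "))
    if (any(fixed <= 0)) stop("clamped Kd values must be > 0")
    mask[names(fixed)] <- TRUE
    vals[names(fixed)] <- fixed
  }
  list(mask = mask, vals = vals)
}

#' Fit dissociation constants by gradient descent
#'
#' Optimises per-factor Kd (in log10 space, keeping Kd > 0) so that
#' iterating the forward model `innerIterations` times from the initial
#' expression state approaches the reference state under the weighted
#' [trnLoss()]. Gradients are central finite differences on log10-Kd.
#' Clamped factors (the `fixed` map) keep their value bit-identically
#' throughout; derivative-factor matrices are evaluated at the optimum.
#'
#' @param model a [TRNModel-class] or compiled model.
#' @param xInit,xRef named expression vectors covering the roster
#'   (initial and reference transcriptomic states).
#' @param config a [fitConfig()].
#' @param fixed named numeric mapping factor ids to clamped Kd values
#'   (simulated continuous activation/inhibition).
#' @param weights optional loss weights (default: reference-proportional).
#' @return a [TRNFit-class].
#' @export
fitKd <- function(model, xInit, xRef, config = fitConfig(),
                  fixed = NULL, weights = NULL) {
  cm <- if (inherits(model, "CompiledTRN")) model else compileTRN(model)
  if (!cm$nT) stop("empty roster")
  roster <- cm$roster
  x0 <- .asState(cm, xInit)
  xr <- .asState(cm, xRef)
  fx <- .resolveFixed(fixed, roster)
  if (is.null(weights)) {
    m <- mean(xr)
    weights <- if (m > 0) xr / m else rep(0, cm$nT)
  }

  kd0 <- rep(config$kdInit, length.out = cm$nT)
  names(kd0) <- roster
  kd0[fx$mask] <- fx$vals[fx$mask]
  logkd <- log10(kd0)
  free <- which(!fx$mask)
  # Ki is the competitors' constant of the precomputed network; it is
  # never learned, so it stays at the initial dissociation constant
  # (Kd/Ki = 1 at initialisation) unless the model carries a table
  ki <- if (is.null(cm$kiFixed)) rep(config$kdInit,
                                     length.out = cm$nT) else cm$kiFixed

  lossAt <- function(lk) {
    kd <- 10^lk
    kd[fx$mask] <- fx$vals[fx$mask]  # exact clamp, no 10^log10 round-trip
    xp <- forwardSimulate(cm, x0, kd, config$innerIterations, ki = ki)
    trnLoss(unname(xp), xr, weights)
  }

  nStep <- config$nSteps
  traj <- matrix(NA_real_, nStep + 1L, cm$nT,
                 dimnames = list(NULL, roster))
  traj[1L, ] <- kd0
  losses <- numeric(nStep + 1L)
  h <- config$fdStep
  for (s in seq_len(nStep)) {
    losses[s] <- lossAt(logkd)
    if (!is.finite(losses[s]))
      stop("non-finite loss at descent step ", s)
    grad <- numeric(cm$nT)
    for (m in free) {
      lp <- logkd; lp[m] <- lp[m] + h
      lm <- logkd; lm[m] <- lm[m] - h
      grad[m] <- (lossAt(lp) - lossAt(lm)) / (2 * h)
    }
    gc_ <- config$gradClip
    if (!is.null(gc_))
      grad <- pmin(pmax(grad, -gc_), gc_)
    # line search along the clipped gradient: the landscape mixes
    # near-flat valleys with steep switch walls, so a fixed rate either
    # crawls or oscillates. All step lengths on the ladder are
    # evaluated and the best strict improvement is taken, keeping the
    # loss trajectory monotone.
    gsq <- sum(grad[free]^2)
    bestLoss <- losses[s]
    bestCand <- NULL
    for (alpha in config$learningRate *
           2^(config$lineSearchMax:(-2L))) {
      cand <- logkd
      cand[free] <- cand[free] - alpha * grad[free]
      lc <- lossAt(cand)
      if (is.finite(lc) && lc < bestLoss - 1e-4 * alpha * gsq) {
        bestLoss <- lc
        bestCand <- cand
      }
    }
    if (!is.null(bestCand)) logkd <- bestCand
    kd <- 10^logkd
    kd[fx$mask] <- fx$vals[fx$mask]
    traj[s + 1L, ] <- kd
  }
  losses[nStep + 1L] <- lossAt(logkd)
  if (!is.finite(losses[nStep + 1L]))
    stop("non-finite loss after final step")

  kdFinal <- traj[nStep + 1L, ]
  state <- forwardSimulate(cm, x0, kdFinal, config$innerIterations,
                           ki = ki)
  dfac <- derivativeFactors(cm, state, kdFinal, ki = ki)

  new("TRNFit", kdTrajectory = traj, kdFinal = kdFinal,
      lossTrajectory = losses, AMatrix = dfac$A, RMatrix = dfac$R,
      fixedMask = fx$mask,
      config = list(nSteps = config$nSteps,
                    learningRate = config$learningRate,
                    innerIterations = config$innerIterations,
                    fdStep = config$fdStep, kdInit = config$kdInit,
                    gradClip = config$gradClip,
                    lineSearchMax = config$lineSearchMax,
                    seed = config$seed, fixed = fixed))
}

#' Derivative factors of the network at a state
#'
#' Central finite differences of each gene's promoter activation term and
#' gene-body repression term with respect to each regulator's
#' concentration: `A[m, g] = d(promoter flux of g) / d x_m` and
#' `R[m, g]` for the (unsigned) gene-body term. These sensitivities are
#' the edge weights of the exported activator/repressor digraphs.
#'
#' @param model a [TRNModel-class] or compiled model.
#' @param state named (or roster-ordered) concentration vector.
#' @param kd roster-ordered dissociation constants.
#' @param ki optional inhibition constants.
#' @param h relative finite-difference step.
#' @return list of matrices `A` and `R` (regulator x target, dimnames set
#'   to the roster).
#' @export
derivativeFactors <- function(model, state, kd, ki = NULL, h = 1e-4) {
  cm <- if (inherits(model, "CompiledTRN")) model else compileTRN(model)
  x <- .asState(cm, state)
  if (is.null(ki)) ki <- .effKi(cm, kd)
  n <- cm$nT
  A <- matrix(0, n, n, dimnames = list(cm$roster, cm$roster))
  R <- matrix(0, n, n, dimnames = list(cm$roster, cm$roster))
  for (m in seq_len(n)) {
    hm <- h * (1 + abs(x[m]))
    xp <- x; xp[m] <- xp[m] + hm
    xm <- x; xm[m] <- max(0, xm[m] - hm)
    dd <- xp[m] - xm[m]
    promP <- .sideFlux(cm$prom, xp, kd, ki, cm$params)
    promM <- .sideFlux(cm$prom, xm, kd, ki, cm$params)
    bodyP <- .sideFlux(cm$body, xp, kd, ki, cm$params)
    bodyM <- .sideFlux(cm$body, xm, kd, ki, cm$params)
    A[m, ] <- (promP - promM) / dd
    # gene-body side fluxes are signed negative; report the unsigned
    # repression sensitivity
    R[m, ] <- -(bodyP - bodyM) / dd
  }
  list(A = A, R = R)
}
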