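test_that("site weights follow the exponential score law", {
  expect_equal(siteWeight(1, 10), 1)
  expect_equal(siteWeight(0.9, 10), 0.1)
  expect_equal(siteWeight(0, 10), 1e-10)
  expect_equal(siteWeight(0.5, exp(1)), 10^(-exp(1) / 2))
  expect_error(siteWeight(1.2, 10), "\\[0, 1\\]")
  expect_error(siteWeight(0.5, -1), "> 0")
})

test_that("occupancy analytic spot values hold", {
  # p saturating sites at A = kd give r = p/2 (competitive regime)
  for (p in 1:4)
    expect_equal(occupancy(rep(1, p), A = 3, kd = 3, a = 10,
                           seThreshold = 5), p / 2)
  expect_equal(occupancy(c(1, 1), A = 0, kd = 1, a = 10), 0)
  # fully symmetric competitive case: A = kd, sq = 1, kd/ki = 1, R = kd
  expect_equal(occupancy(1, A = 2, kd = 2, a = 10, sq = 1, repConc = 2,
                         ki = 2), 1 / 3)
  expect_error(occupancy(rep(1, 5), 1, 1, 10), "at most 4")
})

# independent naive evaluator of the competitive-equilibrium occupancy
naiveOccupancy <- function(sp, A, kd, a, sq, repConc, ki, seThreshold) {
  w <- function(s) 10^(-a * (1 - s))
  if (sum(sp) <= seThreshold) {
    r <- 0
    for (i in seq_along(sp)) {
      rep_ <- if (is.na(sq[i]) || repConc[i] == 0) 0
      else w(sq[i]) * (kd / ki[i]) * repConc[i]
      r <- r + w(sp[i]) * A / (kd + w(sp[i]) * A + rep_)
    }
    r
  } else {
    num <- 0; rep_ <- 0
    for (i in seq_along(sp)) {
      num <- num + w(sp[i]) * A^i
      if (!is.na(sq[i]) && repConc[i] > 0)
        rep_ <- rep_ + w(sq[i]) * (kd / ki[i]) * repConc[i]
    }
    length(sp) * num / (kd^length(sp) + num + rep_)
  }
}

test_that("occupancy matches an independent naive evaluator", {
  set.seed(31)
  for (i in 1:400) {
    p <- sample(1:4, 1)
    sp <- sort(runif(p), decreasing = TRUE)
    hasR <- runif(p) < 0.5
    sq <- ifelse(hasR, runif(p), NA_real_)
    repConc <- ifelse(hasR, runif(p, 0, 5), 0)
    ki <- runif(p, 0.2, 5)
    A <- runif(1, 0, 5)
    kd <- runif(1, 0.1, 5)
    a <- runif(1, 1, 12)
    th <- sample(c(0, 3, 5), 1)  # forces both regimes
    got <- occupancy(sp, A, kd, a, sq, repConc, ki, seThreshold = th)
    want <- naiveOccupancy(sp, A, kd, a, sq, repConc, ki, th)
    expect_equal(got, want, tolerance = 1e-12)
    expect_gte(got, 0)
    expect_lte(got, p)
  }
})

test_that("occupancy is monotone in A, kd and repressor concentration", {
  set.seed(32)
  for (i in 1:40) {
    p <- sample(1:4, 1)
    sp <- sort(runif(p, 0.3, 1), decreasing = TRUE)
    sq <- runif(p); repConc <- runif(p, 0, 3); ki <- runif(p, 0.5, 2)
    A <- runif(1, 0.1, 4); kd <- runif(1, 0.2, 4)
    f <- function(A., kd., rc.) occupancy(sp, A., kd., 8, sq, rc., ki,
                                          seThreshold = 5)
    eps <- 1e-6
    expect_gte(f(A + eps, kd, repConc), f(A, kd, repConc))
    expect_lte(f(A, kd + eps, repConc), f(A, kd, repConc))
    expect_lte(f(A, kd, repConc + eps), f(A, kd, repConc))
  }
})

test_that("activation flux saturates at kc and vanishes at zero occupancy", {
  expect_equal(activatorContribution(0, 2), 0)
  expect_equal(activatorContribution(1, 1), exp(-1))
  expect_equal(activatorContribution(1e9, 3), 3, tolerance = 1e-8)
  expect_true(all(diff(activatorContribution(seq(0.01, 5, 0.01), 1)) > 0))
})

test_that("degradation closed form has the Lambert-W identities", {
  expect_equal(degrade(0, 1), 0)
  expect_equal(degrade(2.5, 0), 2.5, tolerance = 1e-12)  # W(x e^x) = x
  # W(1) by independent bisection on w e^w = 1
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mid * exp(mid) < 1) lo <- mid else hi <- mid
  }
  expect_equal(degrade(1, 1), lo, tolerance = 1e-9)
  # overflow-safe far beyond exp() range
  expect_equal(degrade(1e6, 2), 1e6 - 2, tolerance = 1e-6)
  expect_error(degrade(-1, 1), "non-negative")
})

test_that("degradation agrees with pracma's Lambert W on the safe range", {
  skip_if_not_installed("pracma")
  set.seed(33)
  x <- runif(50, 0.01, 20); d <- runif(50, 0, 5)
  ref <- vapply(seq_along(x), function(i)
    pracma::lambertWp(exp(x[i] + log(x[i]) - d[i])), 0)
  expect_equal(degrade(x, d), ref, tolerance = 1e-9)
})

test_that("degradation matches RK4 integration of Michaelis-Menten decay", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(x = seq(0.5, 10, length.out = 8),
                      d = seq(0.5, 5, length.out = 6))
  for (i in seq_len(nrow(grid))) {
    x0 <- grid$x[i]; d <- grid$d[i]
    sol <- deSolve::rk4(c(x = x0), times = seq(0, 1, by = 0.005),
                        func = function(t, y, p) list(-d * y / (1 + y)),
                        parms = NULL)
    expect_equal(unname(degrade(x0, d)), unname(sol[nrow(sol), "x"]),
                 tolerance = 1e-6)
  }
  # monotone in x, antitone in d
  expect_true(all(diff(degrade(seq(0.1, 5, 0.1), 1)) > 0))
  expect_true(all(diff(degrade(2, seq(0, 3, 0.2))) < 0))
})

test_that("state updates preserve non-negativity and fixed points", {
  prom <- rbind(siteRow("g1", "g2", sp = 1),
                siteRow("g2", "g1", sp = 0.9),
                siteRow("g2", "g2", rank = 1, sp = 0.8))
  m <- tinyModel(prom)
  cm <- compileTRN(m)
  # all-zero state is a fixed point
  z <- setNames(rep(0, 2), roster(m))
  expect_equal(unname(trnStep(cm, z, c(1, 1))), c(0, 0))
  set.seed(34)
  for (i in 1:25) {
    x <- setNames(runif(2, 0, 10), roster(m))
    kd <- runif(2, 0.05, 20)
    nxt <- trnStep(cm, x, kd)
    expect_true(all(nxt >= 0))
  }
})

test_that("pure degradation decays monotonically to zero", {
  prom <- siteRow("g1", "g2", sp = 0)   # negligible weight at a = 30
  m <- tinyModel(prom, params = modelParams(a = 30, d = 1))
  cm <- compileTRN(m)
  tr <- forwardSimulate(cm, setNames(c(5, 3), roster(m)), c(1, 1), 50,
                        keepTrajectory = TRUE)
  expect_true(all(diff(tr[, 1]) < 1e-12))
  expect_lt(tr[51, 1], 1e-3)
})

test_that("a self-activating factor converges to the root-solved fixed point", {
  prom <- rbind(siteRow("g1", "g1", rank = 1, sp = 1),
                siteRow("g1", "g1", rank = 2, offset = 20, sp = 1))
  m <- tinyModel(prom, params = modelParams(a = 10, kc = 1, d = 1))
  cm <- compileTRN(m)
  kd <- 0.2
  xs <- forwardSimulate(cm, c(g1 = 2), kd, 400)
  # independent bracketed root of x - g(x) = f(r(x))
  fp <- uniroot(function(x) {
    r <- 2 * x / (kd + x)
    exp(-1 / r) + degrade(x, 1) - x
  }, c(0.2, 10), tol = 1e-12)$root
  expect_equal(unname(xs), fp, tolerance = 1e-6)
})

test_that("compiled network flux equals per-gene occupancy composition", {
  fx <- smallFixture()
  m <- fx$model
  cm <- compileTRN(m)
  ros <- roster(m)
  set.seed(35)
  x <- setNames(runif(length(ros), 0.1, 4), ros)
  kd <- setNames(runif(length(ros), 0.3, 3), ros)
  ki <- setNames(rep(1, length(ros)), ros)
  got <- geneRegulation(cm, x, kd, ki)
  p <- fx$config$params
  naiveGene <- function(g) {
    sideSum <- function(df, bodySide) {
      df <- df[df$gene_id == g & df$tf_id %in% ros, , drop = FALSE]
      s <- 0
      for (tf in unique(df$tf_id)) {
        dt <- df[df$tf_id == tf, , drop = FALSE]
        dt <- dt[order(dt$site_rank), , drop = FALSE]
        r <- occupancy(dt$sp, x[tf], kd[tf], p@a, dt$sq,
                       ifelse(is.na(dt$repressor_id), 0,
                              x[dt$repressor_id]),
                       ifelse(is.na(dt$repressor_id), 1,
                              ki[dt$repressor_id]),
                       seThreshold = p@seThreshold)
        fl <- activatorContribution(r, p@kc)
        sgn <- if (bodySide) -1 else if (m@repressorOnly[tf]) -1 else 1
        s <- s + sgn * fl
      }
      s
    }
    max(0, sideSum(promoterSites(m), FALSE) +
           sideSum(geneBodySites(m), TRUE))
  }
  for (g in sample(ros, 4))
    expect_equal(unname(got$flux[match(g, ros)]), naiveGene(g),
                 tolerance = 1e-9)
})

test_that("repressor-only factors subtract their promoter contribution", {
  prom <- rbind(siteRow("g1", "act", sp = 1),
                siteRow("g1", "rep", offset = 30, sp = 1))
  m <- tinyModel(prom, roster = c("act", "g1", "rep"),
                 repressorOnly = "rep",
                 params = modelParams(a = 10, kc = 1, d = 1))
  cm <- compileTRN(m)
  x <- c(act = 1, g1 = 1, rep = 1)
  kd <- c(act = 1, g1 = 1, rep = 1)
  reg <- geneRegulation(cm, x, kd)
  # act contributes +e^{-1/r}, rep the same magnitude negatively; both
  # have one saturating site at A = kd, so they cancel exactly
  expect_equal(unname(reg$flux[match("g1", roster(m))]), 0)
  expect_equal(unname(reg$promoter[match("g1", roster(m))]), 0)
})

test_that("gene-body binding represses and the flux clamps at zero", {
  prom <- siteRow("g1", "act", sp = 0.96)
  body <- siteRow("g1", "bodyTF", sp = 1)
  m <- tinyModel(prom, body, roster = c("act", "bodyTF", "g1"),
                 params = modelParams(a = 10, kc = 1, d = 1))
  cm <- compileTRN(m)
  x <- c(act = 1, bodyTF = 1, g1 = 1)
  kd <- c(act = 1, bodyTF = 1, g1 = 1)
  reg <- geneRegulation(cm, x, kd)
  i <- match("g1", roster(m))
  # promoter term (weaker site) < body repression (saturating site)
  expect_lt(reg$promoter[i], -reg$geneBody[i])
  expect_equal(unname(reg$flux[i]), 0)   # clamped, never negative
})

test_that("high weighting exponents silence low-score sites", {
  promFull <- rbind(siteRow("g1", "tf", rank = 1, sp = 1),
                    siteRow("g1", "tf", rank = 2, offset = 20, sp = 0.5),
                    siteRow("g1", "tf", rank = 3, offset = 40, sp = 0.4))
  promTop <- promFull[1, ]
  pars <- modelParams(a = 20, kc = 1, d = 1)
  mF <- tinyModel(promFull, roster = c("g1", "tf"), params = pars)
  mT <- tinyModel(promTop, roster = c("g1", "tf"), params = pars)
  x <- c(g1 = 1, tf = 2); kd <- c(g1 = 1, tf = 1)
  fF <- geneRegulation(compileTRN(mF), x, kd)$flux
  fT <- geneRegulation(compileTRN(mT), x, kd)$flux
  expect_equal(fF, fT, tolerance = 1e-8)
})
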