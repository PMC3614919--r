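test_that("effect-block update interpolates between WLS and full shrinkage", {
  set.seed(42)
  n <- 60
  Z <- matrix(rnorm(n * 3), n, 3)
  w <- runif(n, 0.5, 2)
  r <- rnorm(n)
  # sigma2 -> Inf: weighted least squares
  up <- updateEffectBlock(Z, w, r, 1e12)
  wls <- drop(solve(crossprod(Z, Z * w), crossprod(Z, w * r)))
  expect_equal(up$gamma, wls, tolerance = 1e-4)
  # sigma2 -> 0: effects vanish
  expect_lt(max(abs(updateEffectBlock(Z, w, r, 1e-12)$gamma)), 1e-8)
  # one-column block: the scalar closed form
  z <- Z[, 1, drop = FALSE]
  s2 <- 0.7
  expect_equal(updateEffectBlock(z, w, r, s2)$gamma,
               s2 * sum(z * w * r) / (s2 * sum(z * w * z) + 1))
})

test_that("shrinkage is monotone in the prior precision", {
  set.seed(43)
  Z <- matrix(rnorm(150), 50, 3)
  w <- runif(50, 0.5, 2)
  r <- rnorm(50)
  norms <- sapply(10^seq(2, -4, by = -0.5), function(s2)
    sqrt(sum(updateEffectBlock(Z, w, r, s2)$gamma^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("variance update is the scaled inverse chi-square posterior mode", {
  expect_equal(updateVariance(4, 2, 0, 0), 1)
  expect_equal(updateVariance(0, 3, 0, 0), 1e-10)  # floored
  # numeric maximization of the conditional log-posterior on random inputs
  set.seed(44)
  for (i in 1:10) {
    E <- runif(1, 0.1, 8)
    m <- sample(1:6, 1)
    tau <- runif(1, 0, 3)
    omega <- runif(1, 0, 2)
    grid <- seq(0.001, 10, by = 5e-4)
    lp <- -((m + tau) / 2 + 1) * log(grid) - (E + omega) / (2 * grid)
    # agreement up to the grid's quantization step
    expect_lt(abs(updateVariance(E, m, tau, omega) - grid[which.max(lp)]),
              5e-4)
  }
})

test_that("fixed-effect update is weighted GLS", {
  set.seed(45)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  b0 <- c(1.5, -0.7)
  # interpolation: exact recovery when the residual is X b
  expect_equal(updateBeta(X, runif(40, 0.5, 2), drop(X %*% b0)), b0,
               ignore_attr = TRUE)
  w <- runif(40, 0.2, 3)
  r <- rnorm(40)
  oracle <- drop(solve(crossprod(X, X * w), crossprod(X, w * r)))
  expect_equal(updateBeta(X, w, r), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # unit weights reduce to OLS
  expect_equal(updateBeta(X, rep(1, 40), r), drop(coef(lm(r ~ X - 1))),
               ignore_attr = TRUE)
  expect_error(updateBeta(cbind(X, a2 = X[, 1]), w, r), "rank deficient")
})

test_that("threshold updates climb the likelihood and keep the ordering", {
  set.seed(46)
  freq <- c(1, 2, 4, 2, 1)
  y <- rep(1:5, times = freq * 40)  # 400 obs with exact 1:2:4:2:1 counts
  eta <- numeric(length(y))
  th <- c(-0.9, -0.3, 0.3, 0.9)
  for (i in 1:20) th <- updateThresholds(y, eta, th)$th
  # ML thresholds of an intercept-free ordinal model = empirical cuts
  expect_equal(th, thresholdsFromFrequencies(freq), tolerance = 1e-6)
  # damping contract on random configurations
  for (i in 1:10) {
    y2 <- sample(1:4, 60, replace = TRUE)
    eta2 <- rnorm(60)
    th2 <- sort(runif(3, -1.5, 1.5)) + c(0, 1e-3, 2e-3)
    ll0 <- ordinalLoglik(y2, eta2, th2)
    up <- updateThresholds(y2, eta2, th2)
    expect_true(all(diff(up$th) > 0))
    expect_gte(ordinalLoglik(y2, eta2, up$th), ll0 - 1e-12)
  }
})

test_that("threshold gradient and Hessian match finite differences", {
  set.seed(47)
  y <- sample(1:5, 80, replace = TRUE)
  eta <- rnorm(80, sd = 0.8)
  th <- c(-1.1, -0.4, 0.5, 1.2)
  eps <- 1e-5
  gr <- ordliab:::.thresholdGradient(y, eta, th)
  fd <- sapply(1:4, function(c) {
    tp <- th; tp[c] <- tp[c] + eps
    tm <- th; tm[c] <- tm[c] - eps
    (ordinalLoglik(y, eta, tp) - ordinalLoglik(y, eta, tm)) / (2 * eps)
  })
  expect_equal(gr, fd, tolerance = 1e-6)
  H <- ordliab:::.thresholdHessian(y, eta, th)
  fdH <- sapply(1:4, function(c) {
    tp <- th; tp[c] <- tp[c] + eps
    tm <- th; tm[c] <- tm[c] - eps
    (ordliab:::.thresholdGradient(y, eta, tp) -
       ordliab:::.thresholdGradient(y, eta, tm)) / (2 * eps)
  })
  expect_equal(H, fdH, tolerance = 1e-5)
})

test_that("the EM fit is deterministic under a fixed seed", {
  dat <- quickSimData(n = 100L, seed = 11L)
  cfg <- simConfig(seed = 11L)
  d <- buildDesign(dat$panel, dat$phen, config = cfg)
  f1 <- ebFit(d, cfg)
  f2 <- ebFit(d, cfg)
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@gamma, f2@gamma)
  expect_identical(f1@thresholds, f2@thresholds)
  expect_identical(f1@loglikTrace, f2@loglikTrace)
})

test_that("null data shrink all allelic effects toward zero", {
  hits <- 0L
  runs <- 20L
  for (s in seq_len(runs)) {
    dat <- quickSimData(n = 200L, h2 = 0, nMarkers = 4L, seed = 100L + s)
    cfg <- simConfig(seed = 100L + s)
    d <- buildDesign(dat$panel, dat$phen, config = cfg)
    fit <- suppressWarnings(ebFit(d, cfg))
    if (max(abs(unlist(fit@gamma))) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.95)
})

test_that("a simulated QTL is recovered with the correct allele ordering", {
  dat <- quickSimData(n = 200L, h2 = 0.15, seed = 21L)
  cfg <- simConfig(seed = 21L)
  d <- buildDesign(dat$panel, dat$phen, config = cfg)
  fit <- suppressWarnings(ebFit(d, cfg))
  qtlLocus <- dat$effects[[1]]$locus
  k <- which(d@blocks$locus == qtlLocus & d@blocks$type == "MQ")
  est <- setNames(fit@gamma[[k]], d@alleleLevels[[k]])
  expect_gt(max(abs(est)), 0.1)
  trueEff <- dat$effects[[1]]$effects[names(est)]
  expect_identical(order(est), order(trueEff))
})

test_that("the EM trace converges to a fixed point", {
  dat <- quickSimData(n = 200L, h2 = 0.15, nMarkers = 7L, seed = 31L)
  cfg <- simConfig(seed = 31L, maxIter = 300L)
  d <- buildDesign(dat$panel, dat$phen, config = cfg)
  fit <- ebFit(d, cfg)
  expect_true(fit@converged)
  dt <- abs(diff(fit@loglikTrace))
  expect_lt(dt[length(dt)], 1e-3)
  # cycle-to-cycle movement decays: the tail is quieter than the start
  expect_lt(median(tail(dt, 10)), median(head(dt, 10)))
})

test_that("with many categories the fit approaches the normal-trait analogue",
{
  corAt <- function(C) {
    sc <- presetScenario(1, seed = 3)
    set.seed(33)
    f <- simulateFounders(sc)
    p <- simulatePedigree(sc, f)
    eff <- assignQtlEffects(sc, p)
    am <- alleleMatrix(p)
    g <- numeric(nrow(am))
    for (q in eff) g <- g + unname(q$effects[am[, q$locus]])
    liab <- g + rnorm(length(g))
    brks <- quantile(liab, probs = seq(0, 1, length.out = C + 1))
    brks[1] <- -Inf; brks[C + 1] <- Inf
    y <- as.integer(cut(liab, brks))
    phen <- ordinalPhenotypes(
      data.frame(cultivar = rownames(am), environment = "E1",
                 category = y), C)
    cfg <- simConfig(seed = 3L, maxIter = 300L)
    d <- buildDesign(p, phen, config = cfg)
    fit <- suppressWarnings(ebFit(d, cfg))
    nf <- ordliab:::.normalEbFit(d, as.numeric(scale(liab)), cfg)
    cor(unlist(fit@gamma), unlist(nf$gamma))
  }
  c2 <- corAt(2)
  c9 <- corAt(9)
  expect_gt(c9, 0.95)
  expect_gte(c9, c2)
})
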