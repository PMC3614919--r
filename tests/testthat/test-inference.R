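# A hand-built EBFit over the toy panel, for unit tests of the reporting
# functions that need fitted effects without running the EM loop.
mockFit <- function(gamma1, gamma2 = NULL, env = "E1") {
  p <- toyPanel()
  ph <- toyPhenotypes(env = env)
  d <- buildDesign(p, ph)
  gam <- lapply(d@Z, function(Zk) numeric(ncol(Zk)))
  gam[[1]] <- gamma1
  if (!is.null(gamma2)) gam[[2]] <- gamma2
  new("EBFit", beta = numeric(ncol(d@X)), gamma = gam,
      sigma2 = rep(0.1, length(gam)), thresholds = c(-1, 0, 0.5, 1),
      iterations = 1L, converged = TRUE, loglikTrace = 0,
      design = d, config = modelConfig())
}

test_that("stage-1 selection keeps blocks whose top effect clears the bar", {
  fit0 <- mockFit(c(0, 0))
  expect_equal(nrow(stage1Select(fit0)), 0L)
  fit <- mockFit(c(0.3, -0.01), c(0.04, 0.02, -0.06))
  sel <- stage1Select(fit, threshold = 0.05)
  expect_equal(sel$block, c(1L, 2L))
  expect_equal(sel$maxAbsEffect, c(0.3, 0.06))
  # monotone: raising the threshold never adds a block
  thr <- c(0.01, 0.05, 0.1, 0.2, 0.5)
  sets <- lapply(thr, function(t) stage1Select(fit, t)$block)
  for (i in seq_len(length(thr) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("PVE is the block's fitted variance over total plus unit residual",
{
  fit0 <- mockFit(c(0, 0), c(0.4, -0.1, 0.2))
  expect_equal(pve(fit0, 1), 0)
  # loc1 carries A,B,A,B,A: effects (x, -1.5x) give mean-zero fitted
  # values with sample variance 1.875 x^2; x = sqrt(2/15) makes it 0.25,
  # so a lone block explaining 0.25 yields 100 * 0.25 / 1.25 = 20%
  x <- sqrt(2 / 15)
  fit <- mockFit(c(x, -1.5 * x))
  expect_equal(pve(fit, 1), 20)
  fit2 <- mockFit(c(1, -0.5), c(0.4, -0.1, 0.2))
  vars <- sapply(seq_along(fit2@gamma), function(k)
    var(drop(fit2@design@Z[[k]] %*% fit2@gamma[[k]])))
  expect_equal(pve(fit2, 1), 100 * vars[1] / (sum(vars) + 1))
})

test_that("elite alleles minimize (or maximize) the effect, ties by carriers",
{
  p <- toyPanel()
  eff <- c(A = -0.73, B = 0.2)
  el <- eliteAlleles(eff, p, "loc1", "minimize")
  expect_equal(el$allele, "A")
  expect_equal(el$effect, -0.73)
  expect_equal(el$carrier, "cv1")                    # first in panel order
  expect_setequal(el$carriers, c("cv1", "cv3", "cv5"))
  expect_equal(eliteAlleles(eff, p, "loc1", "maximize")$allele, "B")
  # tie on effect: the allele with more carriers wins (X:2, Y:2, Z:1)
  effTie <- c(X = -0.5, Y = 0.1, Z = -0.5)
  expect_equal(eliteAlleles(effTie, p, "loc2")$allele, "X")
})

test_that("best-cross prediction matches brute force on the toy panel", {
  p <- toyPanel()
  effects <- list(loc1 = c(A = -0.73, B = 0.2),
                  loc2 = c(X = 0.3, Y = -0.4, Z = -0.1))
  ranked <- predictBestCross(effects, p, 2L)
  # brute-force oracle over all 10 pairs
  am <- alleleMatrix(p)
  oracle <- combn(rownames(am), 2, function(pair) {
    sum(sapply(names(effects), function(l) {
      have <- unique(am[pair, l])
      min(effects[[l]][names(effects[[l]]) %in% have])
    }))
  })
  expect_equal(ranked$score[1], min(oracle))
  expect_equal(sort(ranked$score), sort(as.numeric(oracle)))
  # a set carrying every elite allele attains the sum of elite effects
  eliteSum <- sum(sapply(effects, min))
  pyr <- ranked[ranked$pyramidsAllElite, ]
  if (nrow(pyr)) expect_equal(pyr$score[1], eliteSum)
  # larger parent sets can only do at least as well
  s2 <- predictBestCross(effects, p, 2L)$score[1]
  s3 <- predictBestCross(effects, p, 3L)$score[1]
  s4 <- predictBestCross(effects, p, 4L)$score[1]
  expect_true(s3 <= s2 + 1e-12 && s4 <= s3 + 1e-12)
  expect_equal(min(predictBestCross(effects, p, 4L)$score), eliteSum)
  expect_error(predictBestCross(effects, p, 5L), "between 2 and 4")
})

test_that("chi-square independence matches the Pearson oracle", {
  r0 <- chisqIndependence(matrix(10, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  tab <- matrix(c(20, 5, 5, 20), 2, 2)
  r <- chisqIndependence(tab)
  oracle <- chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(oracle$statistic))  # 18 by hand
  expect_equal(r$statistic, 18)
  expect_equal(r$df, 1)
  expect_warning(rz <- chisqIndependence(rbind(tab, c(0, 0))),
                 "zero-margin")
  expect_equal(rz$statistic, r$statistic)
  expect_error(chisqIndependence(matrix(0, 2, 2)), "all-zero")
})

test_that("the full pipeline declares the simulated QTL with its elite allele",
{
  dat <- quickSimData(n = 250L, h2 = 0.2, seed = 61L)
  res <- mapOrdinalQtl(dat$panel, dat$phen, config = simConfig(seed = 61L))
  calls <- qtlCalls(res)
  expect_gte(nrow(calls), 1L)
  top <- calls[which.max(calls$LOD), ]
  expect_equal(top$locus, dat$effects[[1]]$locus)
  expect_gte(top$LOD, 2)
  expect_true(top$PVE >= 0 && top$PVE <= 100)
  # elite allele = allele with the minimum true effect at the QTL
  trueEff <- dat$effects[[1]]$effects
  expect_equal(top$eliteAllele, names(which.min(trueEff)))
  g <- alleleMatrix(dat$panel)[, top$locus]
  expect_true(all(res@carriers[[top$qtl]] %in% names(g)[g == top$eliteAllele]))
  # report writer round-trips the call table
  dir <- withr::local_tempdir()
  writeFitReport(res, dir)
  back <- read.csv(file.path(dir, "qtl_calls.csv"))
  expect_equal(back$locus, calls$locus)
  js <- jsonlite::read_json(file.path(dir, "fit_report.json"))
  expect_equal(length(js$thresholds), 4L)
})

test_that("PVE recovery: a 10% QTL is reported near 10% on average", {
  sc <- simScenario(nFounders = 100, nNonfounders = 500,
                    chromosomes = data.frame(length_cM = 100,
                                             spacing_cM = 10),
                    qtl = data.frame(chromosome = 1, position_cM = 50,
                                     h2 = 0.10),
                    nReplicates = 10, seed = 2)
  pves <- sapply(seq_len(sc@nReplicates), function(r) {
    set.seed(sc@seed + r)
    f <- simulateFounders(sc)
    p <- simulatePedigree(sc, f)
    eff <- assignQtlEffects(sc, p)
    phen <- simulatePhenotypes(p, eff, sc@categoryFreqs)
    cfg <- simConfig(seed = sc@seed + r)
    d <- buildDesign(p, phen, config = cfg)
    fit <- suppressWarnings(ebFit(d, cfg))
    k <- which(d@blocks$locus == names(eff)[1] & d@blocks$type == "MQ")
    pve(fit, k)
  })
  expect_lt(abs(mean(pves) - 10), 3)
})
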