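bigScenario <- function(nFounders = 10000L, nAlleles = 3L)
  simScenario(nFounders = nFounders, nNonfounders = 1L,
              chromosomes = data.frame(length_cM = 20, spacing_cM = 10),
              nAlleles = nAlleles, qtl = NULL)

test_that("founders draw alleles equifrequently and in linkage equilibrium", {
  sc <- bigScenario()
  set.seed(71)
  f <- simulateFounders(sc)
  am <- alleleMatrix(f)
  freqs <- prop.table(table(am[, 1]))
  expect_true(all(abs(freqs - 1 / 3) < 0.02))
  # adjacent loci unassociated by construction
  p <- chisqIndependence(table(am[, 1], am[, 2]))$p
  expect_gt(p, 1e-4)
  set.seed(71)
  expect_identical(alleleMatrix(simulateFounders(sc)), am)
})

test_that("RIL origin switches follow R = 2r / (1 + 2r)", {
  map <- data.frame(locus = c("m1", "m2"), chromosome = 1,
                    position_cM = c(0, 10))
  pa <- c(m1 = "A", m2 = "A")
  pb <- c(m1 = "B", m2 = "B")
  switchRate <- function(d, n = 10000L) {
    map$position_cM <- c(0, d)
    set.seed(72)
    sw <- replicate(n, {
      ril <- simulateRil(pa, pb, map)
      ril[1] != ril[2]
    })
    mean(sw)
  }
  # d = 0: never switches
  expect_equal(switchRate(0, n = 500L), 0)
  # d = 10 cM: closed-form RIL recombination fraction
  r <- (1 - exp(-0.2)) / 2
  R <- 2 * r / (1 + 2 * r)
  obs <- switchRate(10)
  expect_lt(abs(obs - R), 3 * sqrt(R * (1 - R) / 10000))
  # free recombination limit
  expect_lt(abs(switchRate(1e4) - 0.5), 0.02)
  badMap <- data.frame(locus = c("m1", "m2"), chromosome = 1,
                       position_cM = c(10, 0))
  expect_error(simulateRil(pa, pb, badMap), "ordered")
})

test_that("QTL effects are scaled to the target heritability", {
  sc <- simScenario(nFounders = 100L, nNonfounders = 10000L,
                    chromosomes = data.frame(length_cM = 20,
                                             spacing_cM = 10),
                    qtl = data.frame(chromosome = 1, position_cM = 10,
                                     h2 = 0.15))
  set.seed(73)
  f <- simulateFounders(sc)
  p <- simulatePedigree(sc, f)
  eff <- assignQtlEffects(sc, p)
  g <- unname(eff[[1]]$effects[alleleMatrix(p)[, eff[[1]]$locus]])
  sigmaP2 <- 1 / (1 - 0.15)
  expect_lt(abs(mean(g^2) / sigmaP2 - 0.15), 0.01)
  expect_lt(abs(mean(g)), 1e-10)  # centered at realized frequencies
  # h2 = 0 (no QTL) gives no genetic term; doubling effects quadruples
  # the variance by construction of the indicator coding
  expect_equal(mean((2 * g)^2), 4 * mean(g^2))
  expect_error(
    simScenario(nFounders = 10, nNonfounders = 10,
                chromosomes = data.frame(length_cM = 20, spacing_cM = 10),
                qtl = data.frame(chromosome = 1, position_cM = c(0, 10),
                                 h2 = c(0.6, 0.5))),
    "< 1")
})

test_that("phenotype categories match the target frequencies", {
  sc <- bigScenario()
  set.seed(74)
  f <- simulateFounders(sc)
  phen <- simulatePhenotypes(f, list(), c(1, 2, 4, 2, 1))
  props <- prop.table(table(phenoTable(phen)$category))
  expect_true(all(abs(props - c(.1, .2, .4, .2, .1)) < 0.01))
  # binary case: a median split
  phen2 <- simulatePhenotypes(f, list(), c(1, 1))
  expect_lt(abs(mean(phenoTable(phen2)$category == 1L) - 0.5), 0.01)
  # determinism: replaying the whole generation reproduces the data
  set.seed(74)
  f3 <- simulateFounders(sc)
  phen3 <- simulatePhenotypes(f3, list(), c(1, 2, 4, 2, 1))
  expect_identical(phenoTable(phen3), phenoTable(phen))
})

test_that("scenario presets and YAML round-trip agree", {
  sc <- presetScenario(1)
  expect_equal(sc@nFounders, 100L)
  expect_equal(nrow(ordliab:::.scenarioMap(sc)), 33L)  # 11 markers x 3
  expect_equal(sc@qtl$h2, c(0.05, 0.10, 0.15))
  expect_error(presetScenario(9), "case")
  y <- system.file("extdata", "preset_reference.yaml", package = "ordliab")
  sc2 <- readSimScenario(y)
  expect_equal(sc2@chromosomes, sc@chromosomes, ignore_attr = TRUE)
  expect_equal(sc2@qtl$h2, sc@qtl$h2)
})

test_that("a tiny power experiment returns coherent bookkeeping", {
  sc <- simScenario(nFounders = 30L, nNonfounders = 80L,
                    chromosomes = data.frame(length_cM = 40,
                                             spacing_cM = 10),
                    qtl = data.frame(chromosome = 1, position_cM = 20,
                                     h2 = 0.3),
                    nReplicates = 3L, seed = 75L)
  pr <- runPowerExperiment(sc)
  expect_s4_class(pr, "PowerResult")
  expect_equal(nrow(pr@power), 1L)
  expect_true(pr@power$detections <= pr@power$replicates)
  expect_true(is.na(pr@fpr) || (pr@fpr >= 0 && pr@fpr <= 1))
  expect_equal(dim(pr@thresholdEstimates), c(3L - pr@excluded, 4L))
})
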