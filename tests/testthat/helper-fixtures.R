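# Small programmatic fixtures shared across the suite.

toyPanel <- function() {
  a <- matrix(c("A", "B", "A", "B", "A",
                "X", "X", "Y", "Y", "Z"),
              ncol = 2,
              dimnames = list(paste0("cv", 1:5), c("loc1", "loc2")))
  genotypePanel(a, data.frame(locus = c("loc1", "loc2"),
                              chromosome = c("1", "2"),
                              position_cM = c(10, 20)))
}

toyPhenotypes <- function(env = c("E1", "E2")) {
  recs <- expand.grid(cultivar = paste0("cv", 1:5), environment = env,
                      stringsAsFactors = FALSE)
  recs$category <- rep_len(c(1L, 2L, 3L, 2L, 5L), nrow(recs))
  ordinalPhenotypes(recs, nCategories = 5L)
}

# A single-QTL mapping dataset: n lines, one chromosome of nMarkers at
# 10 cM spacing, QTL at the middle marker with the given heritability.
quickSimData <- function(n = 200L, h2 = 0.15, nMarkers = 5L, seed = 1L,
                         categoryFreqs = c(1, 2, 4, 2, 1)) {
  sc <- simScenario(
    nFounders = 50L, nNonfounders = n,
    chromosomes = data.frame(length_cM = (nMarkers - 1L) * 10,
                             spacing_cM = 10),
    qtl = if (h2 > 0)
      data.frame(chromosome = 1,
                 position_cM = 10 * ((nMarkers - 1L) %/% 2L), h2 = h2)
    else NULL,
    categoryFreqs = categoryFreqs, seed = seed)
  set.seed(seed)
  founders <- simulateFounders(sc)
  panel <- simulatePedigree(sc, founders)
  effects <- assignQtlEffects(sc, panel)
  phen <- simulatePhenotypes(panel, effects, categoryFreqs)
  list(scenario = sc, panel = panel, effects = effects, phen = phen)
}

simConfig <- function(seed = 1L, maxIter = 200L)
  modelConfig(maxIter = maxIter, convergenceTol = 1e-5, rngSeed = seed)
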