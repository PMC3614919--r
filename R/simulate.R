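# Pedigree-based validation engine: founder lines in linkage equilibrium
# with equifrequent multi-allelic loci, non-founders bred as recombinant
# inbred lines (RILs) from random founder pairs, liability phenotypes with
# marker-coincident QTL, and the power / false-positive-rate experiment
# harness.

#' Construct a SimScenario
#'
#' @param nFounders,nNonfounders population sizes.
#' @param chromosomes data.frame with columns `length_cM`, `spacing_cM`
#'   (markers at 0, spacing, 2*spacing, ... along each chromosome).
#' @param nAlleles alleles per locus, drawn equifrequently in founders.
#' @param qtl data.frame with columns `chromosome`, `position_cM`, `h2`;
#'   positions must coincide with marker positions.
#' @param categoryFreqs category weights defining the liability cuts.
#' @param nReplicates replicates of a power experiment.
#' @param lodThreshold LOD declaration threshold when scoring detection.
#' @param seed base seed; replicate r uses seed + r.
#' @return a [SimScenario-class]
#' @export
simScenario <- function(nFounders, nNonfounders, chromosomes,
                        nAlleles = 3L, qtl = NULL,
                        categoryFreqs = c(1, 2, 4, 2, 1),
                        nReplicates = 100L, lodThreshold = 2.0,
                        seed = 1L) {
  if (is.null(qtl))
    qtl <- data.frame(chromosome = integer(0), position_cM = numeric(0),
                      h2 = numeric(0))
  sc <- new("SimScenario", nFounders = as.integer(nFounders),
            nNonfounders = as.integer(nNonfounders),
            chromosomes = chromosomes, nAlleles = as.integer(nAlleles),
            qtl = qtl, categoryFreqs = categoryFreqs,
            nReplicates = as.integer(nReplicates),
            lodThreshold = lodThreshold, seed = as.integer(seed))
  map <- .scenarioMap(sc)
  for (i in seq_len(nrow(qtl))) {
    hit <- map$chromosome == qtl$chromosome[i] &
      abs(map$position_cM - qtl$position_cM[i]) < 1e-9
    if (!any(hit))
      stop("QTL ", i, " does not coincide with a marker position")
  }
  sc
}

.scenarioMap <- function(scenario) {
  rows <- lapply(seq_len(nrow(scenario@chromosomes)), function(ch) {
    pos <- seq(0, scenario@chromosomes$length_cM[ch],
               by = scenario@chromosomes$spacing_cM[ch])
    data.frame(locus = sprintf("c%dm%02d", ch, seq_along(pos)),
               chromosome = ch, position_cM = pos)
  })
  do.call(rbind, rows)
}

#' Ready-made power-study scenarios
#'
#' Ready-made scenarios for the power studies: case 1 is the reference
#' design (100 founders, 200 non-founders, three 100 cM chromosomes with
#' 11 markers each at 10 cM spacing, one 3-allele QTL at 50 cM of each
#' chromosome with liability heritabilities 0.05, 0.10 and 0.15, five
#' categories in ratio 1:2:4:2:1). Cases 2 and 3 vary the category
#' distribution and category count, case 4 the sample size, and cases 5
#' and 6 use three 1000 cM chromosomes with 18 QTL and vary sample and
#' founder number.
#'
#' @param case integer 1..6.
#' @param categoryFreqs override the category weights (cases 2-3).
#' @param nFounders,nNonfounders override population sizes (cases 4-6).
#' @param nReplicates,seed experiment controls.
#' @return a [SimScenario-class]
#' @export
presetScenario <- function(case = 1L, categoryFreqs = NULL,
                           nFounders = NULL, nNonfounders = NULL,
                           nReplicates = 100L, seed = 1L) {
  small <- data.frame(length_cM = rep(100, 3), spacing_cM = rep(10, 3))
  big <- data.frame(length_cM = rep(1000, 3), spacing_cM = rep(10, 3))
  smallQtl <- data.frame(chromosome = 1:3, position_cM = c(50, 50, 50),
                         h2 = c(0.05, 0.10, 0.15))
  bigQtl <- data.frame(
    chromosome = rep(1:3, each = 6),
    position_cM = c(90, 240, 390, 540, 690, 840,
                    80, 230, 380, 530, 680, 830,
                    120, 270, 420, 570, 720, 870),
    h2 = c(rep(0.01, 5), rep(0.03, 5), rep(0.05, 6), 0.10, 0.15))
  defaults <- switch(as.character(case),
    "1" = , "2" = , "3" = , "4" =
      list(nF = 100L, nN = 200L, chr = small, qtl = smallQtl),
    "5" = list(nF = 50L, nN = 300L, chr = big, qtl = bigQtl),
    "6" = list(nF = 50L, nN = 200L, chr = big, qtl = bigQtl),
    stop("case must be 1..6"))
  simScenario(
    nFounders = if (is.null(nFounders)) defaults$nF else nFounders,
    nNonfounders = if (is.null(nNonfounders)) defaults$nN else
      nNonfounders,
    chromosomes = defaults$chr, nAlleles = 3L, qtl = defaults$qtl,
    categoryFreqs = if (is.null(categoryFreqs)) c(1, 2, 4, 2, 1) else
      categoryFreqs,
    nReplicates = nReplicates, seed = seed)
}

#' Read a SimScenario from a YAML file
#'
#' Keys: `nFounders`, `nNonfounders`, `chromosomes` (list of maps with
#' `length_cM`, `spacing_cM`), `nAlleles`, `qtl` (list of maps with
#' `chromosome`, `position_cM`, `h2`), `categoryFreqs`, `nReplicates`,
#' `lodThreshold`, `seed`.
#' @param path YAML file.
#' @return a [SimScenario-class]
#' @export
readSimScenario <- function(path) {
  v <- yaml::read_yaml(path)
  v$chromosomes <- do.call(rbind, lapply(v$chromosomes, as.data.frame))
  if (!is.null(v$qtl))
    v$qtl <- do.call(rbind, lapply(v$qtl, as.data.frame))
  v$categoryFreqs <- as.numeric(v$categoryFreqs)
  do.call(simScenario, v)
}

#' Simulate founder genotypes in linkage equilibrium
#'
#' Every founder draws one allele per locus, independently and uniformly
#' over the locus's allele set; loci are mutually independent.
#'
#' @param scenario a [SimScenario-class].
#' @return a [GenotypePanel-class] of founders (ids "F1", "F2", ...).
#' @export
simulateFounders <- function(scenario) {
  map <- .scenarioMap(scenario)
  nf <- scenario@nFounders
  labels <- paste0("A", seq_len(scenario@nAlleles))
  a <- matrix(sample(labels, nf * nrow(map), replace = TRUE),
              nrow = nf,
              dimnames = list(paste0("F", seq_len(nf)), map$locus))
  genotypePanel(a, map)
}

#' Simulate one recombinant inbred line from two homozygous parents
#'
#' A Markov walk along each chromosome: the first marker's parental origin
#' is A or B with probability 1/2; between adjacent markers the origin
#' switches with the RIL (selfed-to-fixation) recombination fraction
#' R = 2r / (1 + 2r), where r = (1 - exp(-2d/100)) / 2 is the Haldane
#' recombination fraction for map distance d cM.
#'
#' @param parentA,parentB named allele vectors over the same loci.
#' @param map data.frame `locus`, `chromosome`, `position_cM`; positions
#'   must be ordered within chromosome.
#' @return named allele vector of the RIL.
#' @export
simulateRil <- function(parentA, parentB, map) {
  out <- parentA
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$position_cM[idx]
    if (is.unsorted(pos, strictly = FALSE))
      stop("marker positions must be ordered within chromosome")
    d <- diff(pos)
    r <- (1 - exp(-2 * d / 100)) / 2
    R <- 2 * r / (1 + 2 * r)
    origin <- integer(length(idx))
    origin[1L] <- sample.int(2L, 1L)
    if (length(idx) > 1L) {
      sw <- runif(length(R)) < R
      for (i in seq_along(sw))
        origin[i + 1L] <- if (sw[i]) 3L - origin[i] else origin[i]
    }
    out[idx] <- ifelse(origin == 1L, parentA[idx], parentB[idx])
  }
  out
}

#' Breed a panel of non-founder RILs from random founder pairs
#'
#' Each non-founder draws two distinct founders uniformly at random and is
#' generated by [simulateRil()].
#'
#' @param scenario a [SimScenario-class].
#' @param founders a [GenotypePanel-class] of founders.
#' @return a [GenotypePanel-class] of non-founders (ids "L1", "L2", ...).
#' @export
simulatePedigree <- function(scenario, founders) {
  map <- markerMap(founders)
  fa <- alleleMatrix(founders)
  n <- scenario@nNonfounders
  a <- matrix(NA_character_, n, ncol(fa),
              dimnames = list(paste0("L", seq_len(n)), colnames(fa)))
  for (i in seq_len(n)) {
    pr <- sample.int(nrow(fa), 2L)
    a[i, ] <- simulateRil(fa[pr[1L], ], fa[pr[2L], ], map)
  }
  genotypePanel(a, map)
}

#' Assign QTL allele effects matching target heritabilities
#'
#' Base effects are equally spaced (-1 ... +1 over the allele set),
#' centered at the realized allele frequencies among the mapping panel and
#' scaled so the QTL's genetic variance equals h2 * sigmaP2, where
#' sigmaP2 = 1 / (1 - sum of h2) is the implied total phenotypic
#' (liability) variance with a unit residual.
#'
#' @param scenario a [SimScenario-class].
#' @param panel the mapping panel (non-founders) whose realized allele
#'   frequencies anchor the scaling.
#' @return named list per QTL: `locus`, `effects` (named vector), `h2`.
#' @export
assignQtlEffects <- function(scenario, panel) {
  if (sum(scenario@qtl$h2) >= 1)
    stop("sum of QTL heritabilities must be < 1")
  sigmaP2 <- 1 / (1 - sum(scenario@qtl$h2))
  map <- markerMap(panel)
  am <- alleleMatrix(panel)
  out <- vector("list", nrow(scenario@qtl))
  for (i in seq_len(nrow(scenario@qtl))) {
    hit <- which(map$chromosome == scenario@qtl$chromosome[i] &
                   abs(map$position_cM - scenario@qtl$position_cM[i]) <
                     1e-9)
    loc <- map$locus[hit[1L]]
    g <- am[, loc]
    alleles <- sort(unique(g))
    base <- seq(-1, 1, length.out = max(length(alleles), 2L))
    base <- setNames(base[seq_along(alleles)], alleles)
    v <- base[g]
    v <- v - mean(v)
    varEmp <- mean(v^2)
    h2 <- scenario@qtl$h2[i]
    s <- if (varEmp > 0) sqrt(h2 * sigmaP2 / varEmp) else 0
    eff <- (base - mean(base[g])) * s
    out[[i]] <- list(locus = loc, effects = eff, h2 = h2)
  }
  names(out) <- vapply(out, `[[`, character(1), "locus")
  out
}

#' Simulate ordinal phenotypes from QTL effects
#'
#' Each line's liability is the sum of its QTL genotypic values plus a
#' standard normal residual; the liability is cut into categories at the
#' thresholds implied by `categoryFreqs`, scaled by the liability standard
#' deviation so the marginal category proportions match the target
#' frequencies whatever the genetic variance.
#'
#' @param panel mapping panel.
#' @param effects list from [assignQtlEffects()].
#' @param categoryFreqs category weights.
#' @param environment environment label for the records (default "E1").
#' @return an [OrdinalPhenotypes-class]
#' @export
simulatePhenotypes <- function(panel, effects,
                               categoryFreqs = c(1, 2, 4, 2, 1),
                               environment = "E1") {
  am <- alleleMatrix(panel)
  n <- nrow(am)
  g <- numeric(n)
  for (q in effects)
    g <- g + unname(q$effects[am[, q$locus]])
  liab <- g + rnorm(n)
  th <- thresholdsFromFrequencies(categoryFreqs) *
    sqrt(mean((g - mean(g))^2) + 1)
  y <- findInterval(liab, th) + 1L
  ordinalPhenotypes(
    data.frame(cultivar = rownames(am), environment = environment,
               category = y),
    nCategories = length(categoryFreqs))
}

#' Run a power / false-positive-rate experiment
#'
#' For each replicate: simulate founders, breed the RIL panel, assign QTL
#' effects, draw phenotypes, and run the full mapping pipeline (EM
#' empirical Bayes fit, stage-1 selection, likelihood-ratio tests). A true
#' QTL counts as detected when its marker's block passes both stages with
#' LOD at or above the scenario threshold; every declared non-QTL block is
#' a false positive. Power per QTL is detections over replicates; the FPR
#' is false positives over (zero-effect blocks x replicates). Replicates
#' whose pipeline fails are excluded and counted.
#'
#' @param scenario a [SimScenario-class].
#' @param config a [ModelConfig-class] for the per-replicate fits; the
#'   replicate seed (scenario seed + replicate index) overrides its
#'   `rngSeed`.
#' @return a [PowerResult-class]
#' @export
runPowerExperiment <- function(scenario,
                               config = modelConfig(maxIter = 200L,
                                                    convergenceTol = 1e-5)) {
  nq <- nrow(scenario@qtl)
  C1 <- length(scenario@categoryFreqs) - 1L
  detect <- matrix(0L, scenario@nReplicates, nq)
  thEst <- matrix(NA_real_, scenario@nReplicates, C1)
  effEst <- vector("list", scenario@nReplicates)
  fp <- 0L
  zeroTotal <- 0L
  excluded <- 0L
  ok <- logical(scenario@nReplicates)
  for (r in seq_len(scenario@nReplicates)) {
    res <- tryCatch({
      set.seed(scenario@seed + r)
      founders <- simulateFounders(scenario)
      panel <- simulatePedigree(scenario, founders)
      effects <- assignQtlEffects(scenario, panel)
      phen <- simulatePhenotypes(panel, effects, scenario@categoryFreqs)
      cfg <- config
      cfg@rngSeed <- scenario@seed + r
      design <- buildDesign(panel, phen, config = cfg)
      fit <- suppressWarnings(ebFit(design, cfg))
      sel <- stage1Select(fit)
      qtlLoci <- names(effects)
      lods <- setNames(numeric(nrow(sel)), design@blocks$locus[sel$block])
      for (i in seq_len(nrow(sel)))
        lods[i] <- lrtLocus(design, sel$block, sel$block[i])$LOD
      passed <- names(lods)[lods >= scenario@lodThreshold]
      list(det = as.integer(qtlLoci %in% passed),
           fp = sum(!passed %in% qtlLoci),
           zero = length(design@Z) - nq,
           th = fit@thresholds,
           eff = lapply(seq_len(nrow(design@blocks)), function(k)
             if (design@blocks$locus[k] %in% qtlLoci &&
                 design@blocks$type[k] == "MQ")
               setNames(fit@gamma[[k]], design@alleleLevels[[k]])))
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { excluded <- excluded + 1L; next }
    ok[r] <- TRUE
    detect[r, ] <- res$det
    fp <- fp + res$fp
    zeroTotal <- zeroTotal + res$zero
    thEst[r, ] <- res$th
    effEst[[r]] <- Filter(Negate(is.null), res$eff)
  }
  nEff <- sum(ok)
  map <- .scenarioMap(scenario)
  markers <- vapply(seq_len(nq), function(i) {
    hit <- which(map$chromosome == scenario@qtl$chromosome[i] &
                   abs(map$position_cM - scenario@qtl$position_cM[i]) <
                     1e-9)
    map$locus[hit[1L]]
  }, character(1))
  power <- data.frame(marker = markers, h2 = scenario@qtl$h2,
                      detections = colSums(detect[ok, , drop = FALSE]),
                      replicates = rep(nEff, nq))
  power$power <- if (nEff) power$detections / nEff else NA_real_
  new("PowerResult", power = power,
      fpr = if (zeroTotal) fp / zeroTotal else NA_real_,
      thresholdEstimates = thEst[ok, , drop = FALSE],
      effectEstimates = effEst[ok],
      excluded = excluded, scenario = scenario)
}
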