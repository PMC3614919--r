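#' @import methods
#' @importFrom stats pnorm dnorm qnorm rnorm runif rgamma var optim
#'   chisq.test setNames pchisq
#' @importFrom utils combn read.table write.table
NULL

UNKNOWN_ALLELE <- NA_character_

#' GenotypePanel: cultivar-by-locus allele assignments
#'
#' Holds the genotypes of a panel of fully homozygous lines (cultivars or
#' recombinant inbred lines) at multi-allelic marker loci such as SSRs.
#' Each line carries exactly one allele label per locus; missing genotypes
#' are stored as `NA` and never counted among a locus's known alleles.
#'
#' @slot alleles character matrix, cultivars in rows (rownames are cultivar
#'   ids), loci in columns (colnames are locus names); `NA` marks an unknown
#'   allele.
#' @slot map data.frame with columns `locus`, `chromosome`, `position_cM`,
#'   one row per column of `alleles` (positions may be `NA` when no genetic
#'   map is available).
#' @export
setClass("GenotypePanel",
  representation(alleles = "matrix", map = "data.frame"))

setValidity("GenotypePanel", function(object) {
  a <- object@alleles
  msg <- character(0)
  if (!is.character(a)) msg <- c(msg, "alleles must be a character matrix")
  if (is.null(rownames(a)) || anyDuplicated(rownames(a)))
    msg <- c(msg, "cultivar ids (rownames) must be present and unique")
  if (is.null(colnames(a)) || anyDuplicated(colnames(a)))
    msg <- c(msg, "locus names (colnames) must be present and unique")
  m <- object@map
  if (!all(c("locus", "chromosome", "position_cM") %in% names(m)))
    msg <- c(msg, "map needs columns locus, chromosome, position_cM")
  else if (!identical(as.character(m$locus), colnames(a)))
    msg <- c(msg, "map$locus must match colnames(alleles) in order")
  if (length(msg)) msg else TRUE
})

#' OrdinalPhenotypes: ordinal grade observations per cultivar and environment
#'
#' Stores observed ordinal categories (grades 1..C) of a trait, one record
#' per cultivar-by-environment combination. All environments share the same
#' category scale.
#'
#' @slot data data.frame with columns `cultivar`, `environment`, `category`
#'   (integer in 1..C); each (cultivar, environment) pair appears at most
#'   once.
#' @slot nCategories integer, the number of ordinal categories C.
#' @export
setClass("OrdinalPhenotypes",
  representation(data = "data.frame", nCategories = "integer"))

setValidity("OrdinalPhenotypes", function(object) {
  d <- object@data
  msg <- character(0)
  if (!all(c("cultivar", "environment", "category") %in% names(d)))
    msg <- c(msg, "data needs columns cultivar, environment, category")
  else {
    if (!is.integer(d$category))
      msg <- c(msg, "category must be integer")
    else if (length(d$category) &&
             (any(d$category < 1L) || any(d$category > object@nCategories)))
      msg <- c(msg, sprintf("categories must lie in 1..%d",
                            object@nCategories))
    if (anyDuplicated(d[c("cultivar", "environment")]))
      msg <- c(msg, "duplicate (cultivar, environment) records")
  }
  if (length(object@nCategories) != 1L || is.na(object@nCategories) ||
      object@nCategories < 2L)
    msg <- c(msg, "nCategories must be a single integer >= 2")
  if (length(msg)) msg else TRUE
})

#' StructureCovariates: population-structure membership proportions
#'
#' The Q matrix produced by an external structure analysis: one row per
#' cultivar of subpopulation membership proportions summing to one. Used as
#' fixed covariates (drop-one coded) in the liability model.
#'
#' @slot q numeric matrix, rownames are cultivar ids, K columns of
#'   proportions; each row sums to 1 within 1e-6.
#' @export
setClass("StructureCovariates", representation(q = "matrix"))

setValidity("StructureCovariates", function(object) {
  q <- object@q
  msg <- character(0)
  if (!is.numeric(q) || ncol(q) < 1L)
    msg <- c(msg, "q must be a numeric matrix with K >= 1 columns")
  if (is.null(rownames(q)) || anyDuplicated(rownames(q)))
    msg <- c(msg, "rownames (cultivar ids) must be present and unique")
  if (is.numeric(q) && nrow(q) && any(abs(rowSums(q) - 1) > 1e-6))
    msg <- c(msg, "each row of Q must sum to 1 (tolerance 1e-6)")
  if (length(msg)) msg else TRUE
})

#' ModelConfig: tuning constants of the liability model fit
#'
#' @slot tau,omega nonnegative hyperprior constants of the scaled inverse
#'   chi-square prior on each effect-block variance; (0, 0) gives the
#'   non-informative posterior mode E/(m + 2).
#' @slot stage1Threshold minimum absolute allelic effect (liability scale)
#'   for a block to enter the second-stage likelihood-ratio test.
#' @slot lodThreshold LOD declaration threshold (default 2.0).
#' @slot maxIter,convergenceTol outer-loop cap and parameter-change
#'   tolerance of the EM empirical Bayes fit.
#' @slot weightFloor lower bound on pseudo-data weights.
#' @slot modelUnknownAllele logical; when TRUE an unknown genotype is
#'   modelled as its own allele class instead of contributing zero.
#' @slot betaInit "uniform" (seeded random) or "zero" initialization of the
#'   fixed effects.
#' @slot rngSeed integer seed for all stochastic initialization (NA for
#'   none).
#' @export
setClass("ModelConfig",
  representation(tau = "numeric", omega = "numeric",
                 stage1Threshold = "numeric", lodThreshold = "numeric",
                 maxIter = "integer", convergenceTol = "numeric",
                 weightFloor = "numeric", modelUnknownAllele = "logical",
                 betaInit = "character", rngSeed = "integer"),
  prototype(tau = 0, omega = 0, stage1Threshold = 0.05, lodThreshold = 2.0,
            maxIter = 1000L, convergenceTol = 1e-6, weightFloor = 1e-8,
            modelUnknownAllele = FALSE, betaInit = "uniform",
            rngSeed = 1L))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@tau < 0 || object@omega < 0)
    msg <- c(msg, "tau and omega must be >= 0")
  if (object@lodThreshold <= 0) msg <- c(msg, "lodThreshold must be > 0")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@weightFloor <= 0) msg <- c(msg, "weightFloor must be > 0")
  if (!object@betaInit %in% c("uniform", "zero"))
    msg <- c(msg, "betaInit must be 'uniform' or 'zero'")
  if (length(msg)) msg else TRUE
})

#' DesignBlocks: fixed design and per-locus random-effect blocks
#'
#' One observation row per (cultivar, environment) phenotype record. The
#' fixed part X holds drop-first environment indicators and K-1 structure
#' covariates (the baseline location is absorbed into the thresholds).
#' Each random block is either the main-effect (MQ) allele-indicator matrix
#' of one locus or, with two or more environments, the allele-by-environment
#' (QE) indicator matrix of one locus.
#'
#' @slot X numeric matrix of fixed covariates (may have zero columns).
#' @slot Z list of numeric indicator matrices, one per random block.
#' @slot blocks data.frame with columns `locus`, `type` ("MQ"/"QE"),
#'   `ncol` describing each element of `Z`.
#' @slot y integer vector of observed categories per row.
#' @slot obs data.frame with columns `cultivar`, `environment` per row.
#' @slot environments character vector of environment levels (first is the
#'   baseline absorbed into the thresholds).
#' @slot nCategories integer.
#' @slot alleleLevels list: for each block, the allele labels (or
#'   allele:environment labels) naming its columns.
#' @export
setClass("DesignBlocks",
  representation(X = "matrix", Z = "list", blocks = "data.frame",
                 y = "integer", obs = "data.frame",
                 environments = "character", nCategories = "integer",
                 alleleLevels = "list"))

#' EBFit: state of the empirical Bayes liability-model fit
#'
#' @slot beta fixed-effect estimates (length ncol(X)).
#' @slot gamma list of per-block effect vectors.
#' @slot sigma2 per-block variance estimates.
#' @slot thresholds C-1 strictly increasing liability cut points.
#' @slot iterations outer iterations used.
#' @slot converged logical.
#' @slot loglikTrace exact ordinal log-likelihood per outer iteration.
#' @slot design the DesignBlocks the model was fitted to.
#' @slot config the ModelConfig used.
#' @export
setClass("EBFit",
  representation(beta = "numeric", gamma = "list", sigma2 = "numeric",
                 thresholds = "numeric", iterations = "integer",
                 converged = "logical", loglikTrace = "numeric",
                 design = "DesignBlocks", config = "ModelConfig"))

#' OrdinalQtlResult: declared QTL with test statistics and elite alleles
#'
#' @slot calls data.frame, one row per declared QTL: locus, type, LR, LOD,
#'   PVE (percent), block variance, fitted-effect variance, elite allele,
#'   elite effect, representative carrier.
#' @slot alleleEffects named list of per-allele effect vectors per call.
#' @slot carriers named list of all carriers of each call's elite allele.
#' @slot selected data.frame of stage-1 selected blocks.
#' @slot fit the underlying EBFit.
#' @export
setClass("OrdinalQtlResult",
  representation(calls = "data.frame", alleleEffects = "list",
                 carriers = "list", selected = "data.frame", fit = "EBFit"))

#' SimScenario: parameters of a pedigree simulation experiment
#'
#' Describes a validation scenario: founder lines in linkage equilibrium
#' with equifrequent multi-allelic loci, non-founders bred as recombinant
#' inbred lines from random founder pairs, QTL placed on markers with given
#' liability heritabilities, and phenotypes discretised by threshold cuts
#' derived from target category frequencies.
#'
#' @slot nFounders,nNonfounders population sizes.
#' @slot chromosomes data.frame with columns `length_cM`, `spacing_cM`.
#' @slot nAlleles alleles per locus (founders draw uniformly).
#' @slot qtl data.frame with columns `chromosome`, `position_cM`, `h2`.
#' @slot categoryFreqs nonnegative category weights defining thresholds.
#' @slot nReplicates replicate count of a power experiment.
#' @slot lodThreshold declaration threshold used when scoring detection.
#' @slot seed base RNG seed; replicate r uses seed + r.
#' @export
setClass("SimScenario",
  representation(nFounders = "integer", nNonfounders = "integer",
                 chromosomes = "data.frame", nAlleles = "integer",
                 qtl = "data.frame", categoryFreqs = "numeric",
                 nReplicates = "integer", lodThreshold = "numeric",
                 seed = "integer"),
  prototype(nAlleles = 3L, nReplicates = 100L, lodThreshold = 2.0,
            seed = 1L))

setValidity("SimScenario", function(object) {
  msg <- character(0)
  if (object@nFounders < 2L) msg <- c(msg, "need at least 2 founders")
  if (object@nNonfounders < 1L) msg <- c(msg, "need at least 1 non-founder")
  if (!all(c("length_cM", "spacing_cM") %in% names(object@chromosomes)))
    msg <- c(msg, "chromosomes needs columns length_cM, spacing_cM")
  if (nrow(object@qtl)) {
    if (!all(c("chromosome", "position_cM", "h2") %in% names(object@qtl)))
      msg <- c(msg, "qtl needs columns chromosome, position_cM, h2")
    else {
      if (any(object@qtl$h2 <= 0) || any(object@qtl$h2 >= 1))
        msg <- c(msg, "each h2 must lie in (0, 1)")
      if (sum(object@qtl$h2) >= 1)
        msg <- c(msg, "sum of QTL heritabilities must be < 1")
    }
  }
  if (length(object@categoryFreqs) < 2L || any(object@categoryFreqs < 0) ||
      sum(object@categoryFreqs) <= 0)
    msg <- c(msg, "categoryFreqs must be >= 2 nonnegative weights, sum > 0")
  if (length(msg)) msg else TRUE
})

#' PowerResult: power and false-positive summary of a simulation experiment
#'
#' @slot power data.frame per true QTL: marker, h2, detections, replicates,
#'   power.
#' @slot fpr false positives over total zero-effect blocks across
#'   replicates.
#' @slot thresholdEstimates matrix (replicates x C-1) of fitted thresholds.
#' @slot effectEstimates list per replicate of fitted effects at true QTL.
#' @slot excluded number of replicates dropped for pipeline failure.
#' @slot scenario the SimScenario run.
#' @export
setClass("PowerResult",
  representation(power = "data.frame", fpr = "numeric",
                 thresholdEstimates = "matrix", effectEstimates = "list",
                 excluded = "integer", scenario = "SimScenario"))
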