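# Readers, writers and constructors for the domain types. Delimited files
# are comma- or tab-separated (auto-detected); missing genotype tokens are
# "", "NA" and "-".

MISSING_TOKENS <- c("", "NA", "-")

.detectSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Construct a GenotypePanel
#'
#' @param alleles character matrix of allele labels, cultivars in rows,
#'   loci in columns; `NA` marks an unknown genotype.
#' @param map optional data.frame `locus`, `chromosome`, `position_cM`; a
#'   placeholder map with NA positions is built when absent.
#' @return a [GenotypePanel-class]
#' @export
genotypePanel <- function(alleles, map = NULL) {
  storage.mode(alleles) <- "character"
  if (is.null(map))
    map <- data.frame(locus = colnames(alleles),
                      chromosome = NA_character_,
                      position_cM = NA_real_)
  map <- map[match(colnames(alleles), map$locus), , drop = FALSE]
  rownames(map) <- NULL
  new("GenotypePanel", alleles = alleles, map = map)
}

#' Read a genotype table
#'
#' First column cultivar id, remaining columns one per marker locus; cells
#' are allele labels or a missing token ("", "NA", "-").
#'
#' @param path delimited file (comma or tab, auto-detected).
#' @param map optional marker map data.frame or path to a CSV with columns
#'   `locus` (or `marker`), `chromosome`, `position_cM`.
#' @return a [GenotypePanel-class]. A locus whose genotypes are all unknown
#'   is retained but triggers a warning (it is skipped when the design is
#'   built).
#' @export
readGenotypes <- function(path, map = NULL) {
  d <- read.table(path, header = TRUE, sep = .detectSep(path),
                  colClasses = "character", check.names = FALSE)
  if (ncol(d) < 2L) stop("genotype table needs an id column and >= 1 locus")
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate cultivar id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a <- as.matrix(d[, -1L, drop = FALSE])
  a[a %in% MISSING_TOKENS] <- NA_character_
  rownames(a) <- ids
  if (is.character(map)) {
    m <- read.table(map, header = TRUE, sep = .detectSep(map),
                    check.names = FALSE)
    names(m)[names(m) == "marker"] <- "locus"
    map <- m
  }
  empty <- colnames(a)[colSums(!is.na(a)) == 0L]
  if (length(empty))
    warning("locus with no known alleles (excluded from mapping): ",
            paste(empty, collapse = ", "))
  genotypePanel(a, map)
}

#' Write a genotype table
#' @param panel a [GenotypePanel-class]
#' @param path output file; tab-separated when the extension is .tsv.
#' @export
writeGenotypes <- function(panel, path) {
  a <- alleleMatrix(panel)
  d <- data.frame(cultivar = rownames(a), a, check.names = FALSE)
  write.table(d, path, sep = if (grepl("\\.tsv$", path)) "\t" else ",",
              row.names = FALSE, quote = FALSE, na = "NA")
}

#' Construct OrdinalPhenotypes
#'
#' @param data data.frame with columns `cultivar`, `environment`,
#'   `category`.
#' @param nCategories total category count C; inferred as the maximum
#'   observed category when NULL.
#' @return an [OrdinalPhenotypes-class]
#' @export
ordinalPhenotypes <- function(data, nCategories = NULL) {
  d <- data.frame(cultivar = as.character(data$cultivar),
                  environment = as.character(data$environment),
                  category = data$category)
  if (!is.numeric(d$category) || any(d$category != round(d$category)))
    stop("categories must be integers")
  d$category <- as.integer(d$category)
  if (is.null(nCategories)) nCategories <- max(d$category)
  new("OrdinalPhenotypes", data = d, nCategories = as.integer(nCategories))
}

#' Read an ordinal phenotype table
#'
#' Expects columns `cultivar`, `environment`, `category` (header required;
#' extra columns ignored).
#'
#' @param path delimited file.
#' @param nCategories C, inferred as the maximum category when NULL.
#' @return an [OrdinalPhenotypes-class]
#' @export
readPhenotypes <- function(path, nCategories = NULL) {
  d <- read.table(path, header = TRUE, sep = .detectSep(path),
                  check.names = FALSE)
  need <- c("cultivar", "environment", "category")
  if (!all(need %in% names(d)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  ordinalPhenotypes(d[need], nCategories)
}

#' Write an ordinal phenotype table
#' @param phen an [OrdinalPhenotypes-class]
#' @param path output file.
#' @export
writePhenotypes <- function(phen, path) {
  write.table(phenoTable(phen), path,
              sep = if (grepl("\\.tsv$", path)) "\t" else ",",
              row.names = FALSE, quote = FALSE)
}

#' Bin tolerance-index fractions into five ordinal grades
#'
#' Converts a tolerance index (a treated-over-control trait ratio in
#' \[0, 1\]) into grades 1..5 by the 20% bins 0-20, 20-40, 40-60, 60-80 and
#' 80-100%. Bins are left-open/right-closed with grade 1 including 0
#' exactly; indices above 1 are clamped to grade 5 with a warning.
#'
#' @param index data.frame with columns `cultivar`, `environment`, `index`
#'   (fractions in \[0, 1\]).
#' @return an [OrdinalPhenotypes-class] with 5 categories.
#' @examples
#' gradesFromIndex(data.frame(cultivar = "c1", environment = "e1",
#'                            index = 0.35))
#' @export
gradesFromIndex <- function(index) {
  v <- index$index
  if (any(v < 0)) stop("negative tolerance index")
  if (any(v > 1)) {
    warning("index value(s) > 1 clamped to grade 5")
    v <- pmin(v, 1)
  }
  g <- pmax(1L, as.integer(ceiling(round(v / 0.2, 12))))
  ordinalPhenotypes(data.frame(cultivar = index$cultivar,
                               environment = index$environment,
                               category = g),
                    nCategories = 5L)
}

#' Construct StructureCovariates
#' @param q numeric matrix of membership proportions, rownames cultivar
#'   ids; rows must sum to 1.
#' @return a [StructureCovariates-class]
#' @export
structureCovariates <- function(q) {
  new("StructureCovariates", q = as.matrix(q))
}

#' Read a Q matrix (population-structure covariates)
#'
#' First column cultivar id, remaining K columns membership proportions.
#' @param path delimited file.
#' @return a [StructureCovariates-class]
#' @export
readStructureCovariates <- function(path) {
  d <- read.table(path, header = TRUE, sep = .detectSep(path),
                  check.names = FALSE)
  q <- as.matrix(d[, -1L, drop = FALSE])
  rownames(q) <- as.character(d[[1L]])
  structureCovariates(q)
}

#' Construct a ModelConfig
#'
#' @param tau,omega scaled inverse chi-square hyperprior constants
#'   (default 0, 0: the non-informative posterior mode).
#' @param stage1Threshold minimum absolute effect for stage-1 selection.
#' @param lodThreshold LOD declaration threshold.
#' @param maxIter,convergenceTol EM loop controls.
#' @param weightFloor pseudo-data weight floor.
#' @param modelUnknownAllele model unknown genotypes as an allele class.
#' @param betaInit "uniform" or "zero".
#' @param rngSeed integer seed (NA disables seeding).
#' @return a [ModelConfig-class]
#' @export
modelConfig <- function(tau = 0, omega = 0, stage1Threshold = 0.05,
                        lodThreshold = 2.0, maxIter = 1000L,
                        convergenceTol = 1e-6, weightFloor = 1e-8,
                        modelUnknownAllele = FALSE, betaInit = "uniform",
                        rngSeed = 1L) {
  new("ModelConfig", tau = tau, omega = omega,
      stage1Threshold = stage1Threshold, lodThreshold = lodThreshold,
      maxIter = as.integer(maxIter), convergenceTol = convergenceTol,
      weightFloor = weightFloor, modelUnknownAllele = modelUnknownAllele,
      betaInit = betaInit, rngSeed = as.integer(rngSeed))
}

#' Read a ModelConfig from a YAML file
#'
#' Keys mirror the arguments of [modelConfig()]; absent keys keep their
#' defaults.
#' @param path YAML file.
#' @return a [ModelConfig-class]
#' @export
readModelConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(modelConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(modelConfig, vals)
}
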