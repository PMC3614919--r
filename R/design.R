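# Design construction: one observation row per (cultivar, environment)
# phenotype record; fixed covariates for environment and population
# structure; one random block per locus (MQ) and, with >= 2 environments,
# one per locus (QE).

#' Build the liability-model design
#'
#' The fixed part contains drop-first environment indicators (E-1 columns;
#' the baseline environment's location is absorbed into the thresholds, so
#' no global intercept is used) and K-1 population-structure covariates
#' (one Q column dropped because rows sum to one). Each locus with at least
#' one known allele contributes a main-effect (MQ) block with one indicator
#' column per known allele; with two or more environments it also
#' contributes a QTL-by-environment (QE) block whose columns are the
#' elementwise products of its allele indicators with each environment
#' indicator. A cultivar with an unknown genotype at a locus has all-zero
#' rows in that locus's blocks unless `modelUnknownAllele` is set, in which
#' case the unknown label is treated as an additional allele class.
#'
#' @param panel a [GenotypePanel-class].
#' @param phen an [OrdinalPhenotypes-class]; every cultivar must be present
#'   in `panel`.
#' @param q optional [StructureCovariates-class].
#' @param config a [ModelConfig-class] (controls `modelUnknownAllele`).
#' @return a [DesignBlocks-class]
#' @export
buildDesign <- function(panel, phen, q = NULL, config = modelConfig()) {
  d <- phenoTable(phen)
  ids <- cultivarNames(panel)
  missing <- setdiff(unique(d$cultivar), ids)
  if (length(missing))
    stop("cultivar(s) in phenotypes absent from genotype panel: ",
         paste(missing, collapse = ", "))
  n <- nrow(d)
  rowIdx <- match(d$cultivar, ids)
  envs <- sort(unique(d$environment))
  E <- length(envs)

  # fixed part: drop-first environment dummies, then K-1 Q columns
  X <- matrix(0, n, 0)
  if (E > 1L) {
    Xe <- vapply(envs[-1L], function(e) as.numeric(d$environment == e),
                 numeric(n))
    colnames(Xe) <- paste0("env", envs[-1L])
    X <- cbind(X, Xe)
  }
  if (!is.null(q)) {
    qm <- q@q
    bad <- setdiff(unique(d$cultivar), rownames(qm))
    if (length(bad))
      stop("cultivar(s) missing from Q matrix: ",
           paste(bad, collapse = ", "))
    if (ncol(qm) > 1L) {
      Xq <- qm[rowIdx, -ncol(qm), drop = FALSE]
      colnames(Xq) <- paste0("Q", seq_len(ncol(qm) - 1L))
      rownames(Xq) <- NULL
      X <- cbind(X, Xq)
    }
  }

  am <- alleleMatrix(panel)
  if (config@modelUnknownAllele) {
    am[is.na(am)] <- "<unknown>"
  }
  Z <- list()
  blocks <- data.frame(locus = character(0), type = character(0),
                       ncol = integer(0))
  alleleLevels <- list()
  loci <- lociNames(panel)
  # main-effect blocks in genome order (input column order)
  for (loc in loci) {
    g <- am[rowIdx, loc]
    alleles <- sort(unique(g[!is.na(g)]))
    if (!length(alleles)) next  # empty locus: excluded from mapping
    Zk <- vapply(alleles, function(a) as.numeric(!is.na(g) & g == a),
                 numeric(n))
    Zk <- matrix(Zk, nrow = n,
                 dimnames = list(NULL, paste0(loc, ":", alleles)))
    Z[[length(Z) + 1L]] <- Zk
    blocks <- rbind(blocks, data.frame(locus = loc, type = "MQ",
                                       ncol = ncol(Zk)))
    alleleLevels[[length(alleleLevels) + 1L]] <- alleles
  }
  # QE blocks after all MQ blocks, same locus order
  if (E > 1L) {
    nMQ <- length(Z)
    for (k in seq_len(nMQ)) {
      loc <- blocks$locus[k]
      Zmq <- Z[[k]]
      alleles <- alleleLevels[[k]]
      cols <- lapply(envs, function(e) Zmq * (d$environment == e))
      Zqe <- do.call(cbind, cols)
      labs <- as.vector(outer(alleles, envs,
                              function(a, e) paste0(a, "x", e)))
      colnames(Zqe) <- paste0(loc, ":", labs)
      Z[[length(Z) + 1L]] <- Zqe
      blocks <- rbind(blocks, data.frame(locus = loc, type = "QE",
                                         ncol = ncol(Zqe)))
      alleleLevels[[length(alleleLevels) + 1L]] <- labs
    }
  }
  rownames(blocks) <- NULL
  new("DesignBlocks", X = X, Z = Z, blocks = blocks,
      y = d$category, obs = d[c("cultivar", "environment")],
      environments = envs, nCategories = nCategories(phen),
      alleleLevels = alleleLevels)
}
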