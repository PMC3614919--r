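# Maximum-likelihood ordinal probit fits for the second-stage
# likelihood-ratio test. The reduced model contains the fixed covariates
# plus the stage-1-selected blocks as unpenalized effects, coded
# identifiably: allele effects are only determined relative to a reference
# allele once the thresholds absorb the location, so each MQ block drops
# its first allele column, and each QE block drops its reference allele
# within every environment (and the baseline environment entirely when the
# locus's MQ block is also in the model).

.mlDesign <- function(design, blockIdx) {
  blockIdx <- sort(unique(blockIdx))
  cols <- list()
  groups <- vector("list", length(blockIdx))
  names(groups) <- as.character(blockIdx)
  M <- design@X
  p0 <- ncol(M)
  info <- design@blocks
  envs <- design@environments
  E <- length(envs)
  for (i in seq_along(blockIdx)) {
    k <- blockIdx[i]
    Zk <- design@Z[[k]]
    m <- ncol(Zk)
    if (info$type[k] == "MQ") {
      keep <- if (m >= 2L) 2:m else integer(0)
    } else {
      nAll <- m / E  # columns are env-major: all alleles per environment
      alleleOf <- rep(seq_len(nAll), times = E)
      envOf <- rep(seq_len(E), each = nAll)
      hasMQ <- any(info$type[blockIdx] == "MQ" &
                     info$locus[blockIdx] == info$locus[k])
      keep <- which(alleleOf != 1L & (!hasMQ | envOf != 1L))
    }
    if (length(keep)) {
      sel <- Zk[, keep, drop = FALSE]
      groups[[i]] <- ncol(M) + seq_len(ncol(sel))
      M <- cbind(M, sel)
    } else groups[[i]] <- integer(0)
  }
  list(M = M, groups = groups, nFixed = p0)
}

# Score of the ordinal log-likelihood in the linear predictor, per
# observation.
.etaScore <- function(y, eta, th) {
  cuts <- c(-Inf, th, Inf)
  a <- cuts[y] - eta
  b <- cuts[y + 1L] - eta
  p <- pmax(pnorm(b) - pnorm(a), PROB_FLOOR)
  (dnorm(a) - dnorm(b)) / p
}

#' Maximum-likelihood fit of an ordinal probit model
#'
#' Joint quasi-Newton (BFGS with analytic gradient) maximization of the
#' exact ordinal log-likelihood over regression coefficients and
#' thresholds; the thresholds are parameterized as (t_1, log successive
#' differences) so the strict ordering is maintained throughout.
#'
#' @param y integer categories 1..C.
#' @param M model matrix (no intercept; the thresholds absorb location).
#' @param nCat number of categories C.
#' @param startTh optional starting thresholds (default: observed
#'   frequency quantiles).
#' @return list with `coef`, `th`, `loglik`, `converged`.
#' @export
mlOrdinalFit <- function(y, M, nCat, startTh = NULL) {
  p <- ncol(M)
  C1 <- nCat - 1L
  if (is.null(startTh)) {
    freqs <- tabulate(y, nbins = nCat)
    freqs[freqs == 0L] <- 0.5
    startTh <- thresholdsFromFrequencies(freqs)
  }
  pack <- function(coef, th)
    c(coef, th[1L], if (C1 > 1L) log(diff(th)))
  unpackTh <- function(par) {
    t1 <- par[p + 1L]
    if (C1 > 1L) {
      # clamp so exploratory line-search steps cannot underflow to tied
      # cuts or overflow to infinite ones
      d <- pmin(pmax(exp(par[(p + 2L):(p + C1)]), 1e-8), 1e6)
      cumsum(c(t1, d))
    } else t1
  }
  nll <- function(par) {
    th <- unpackTh(par)
    eta <- if (p) drop(M %*% par[seq_len(p)]) else numeric(length(y))
    -ordinalLoglik(y, eta, th)
  }
  # chain rule for the log-diff parameterization: t_c = t1 + sum of the
  # first c-1 exponentiated differences
  gr <- function(par) {
    th <- unpackTh(par)
    eta <- if (p) drop(M %*% par[seq_len(p)]) else numeric(length(y))
    g <- .etaScore(y, eta, th)
    gc <- if (p) -drop(crossprod(M, g)) else numeric(0)
    G <- .thresholdGradient(y, eta, th)
    gt <- numeric(C1)
    gt[1L] <- sum(G)                      # d l / d t1
    if (C1 > 1L)
      for (i in 2:C1)
        gt[i] <- exp(par[p + i]) * sum(G[i:C1])  # d l / d log-diff_{i-1}
    c(gc, -gt)
  }
  par0 <- pack(numeric(p), startTh)
  opt <- optim(par0, nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0)
    opt <- optim(opt$par, nll, gr, method = "BFGS",
                 control = list(maxit = 5000, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("ordinal ML fit did not converge (optim code ",
         opt$convergence, ", nll ", format(opt$value), ")")
  list(coef = if (p) setNames(opt$par[seq_len(p)], colnames(M)) else
         numeric(0),
       th = unpackTh(opt$par), loglik = -opt$value,
       converged = opt$convergence == 0)
}

#' Likelihood-ratio test of one selected block
#'
#' Fits the reduced ordinal probit model (fixed covariates plus all
#' stage-1-selected blocks, unpenalized, identifiable coding) by maximum
#' likelihood with and without the target block; LR = 2(logL_full -
#' logL_null), floored at 0, and LOD = LR / (2 ln 10).
#'
#' @param design a [DesignBlocks-class].
#' @param selected integer indices of stage-1-selected blocks.
#' @param target the block under test (must be among `selected`).
#' @return list with `LR`, `LOD`, `loglikFull`, `loglikNull`, `df`.
#' @export
lrtLocus <- function(design, selected, target) {
  if (!target %in% selected)
    stop("target block is not among the selected blocks")
  y <- design@y
  full <- .mlDesign(design, selected)
  fitF <- mlOrdinalFit(y, full$M, design@nCategories)
  nullIdx <- setdiff(selected, target)
  red <- .mlDesign(design, nullIdx)
  fitN <- mlOrdinalFit(y, red$M, design@nCategories)
  df <- length(full$groups[[as.character(target)]])
  LR <- max(0, 2 * (fitF$loglik - fitN$loglik))
  list(LR = LR, LOD = LR / (2 * log(10)), loglikFull = fitF$loglik,
       loglikNull = fitN$loglik, df = df)
}
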