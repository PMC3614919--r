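# Expectation-maximization empirical Bayes estimation of the liability
# model: effects block by block as ridge-type posterior means under the
# pseudo-data approximation, block variances as scaled inverse chi-square
# posterior modes, fixed effects by weighted GLS, thresholds by damped
# Newton-Raphson on the exact ordinal likelihood.

SIGMA2_FLOOR <- 1e-10

#' Empirical Bayes update of one effect block
#'
#' Posterior mean and covariance of block k's effects given the current
#' pseudo-data and all other parameters: with W = diag(w) and partial
#' residual r excluding block k,
#' gammaHat = (Z'WZ + I/sigma2)^-1 Z'W r, C = (Z'WZ + I/sigma2)^-1, and
#' the EM quadratic term E(gamma'gamma) = gammaHat'gammaHat + trace(C).
#'
#' @param Zk block indicator matrix (n x m).
#' @param w pseudo-data weights.
#' @param r partial residual (ystar minus all other fitted terms).
#' @param sigma2k current block variance.
#' @return list with `gamma`, `Equad`, `trace`.
#' @export
updateEffectBlock <- function(Zk, w, r, sigma2k) {
  m <- ncol(Zk)
  A <- crossprod(Zk, Zk * w) + diag(1 / sigma2k, m)
  R <- tryCatch(chol(A), error = function(e)
    stop("singular system in effect-block update: ", conditionMessage(e)))
  gamma <- backsolve(R, forwardsolve(t(R), crossprod(Zk, w * r)))
  Cinv <- chol2inv(R)
  gamma <- drop(gamma)
  list(gamma = gamma, Equad = sum(gamma^2) + sum(diag(Cinv)),
       trace = sum(diag(Cinv)))
}

#' Posterior-mode update of a block variance
#'
#' Mode of the conditional scaled inverse chi-square posterior of sigma2_k:
#' (E(gamma'gamma) + omega) / (m_k + 2 + tau), floored at 1e-10.
#'
#' @param Equad expectation of the quadratic term gamma'gamma.
#' @param m block dimension.
#' @param tau,omega hyperprior constants.
#' @return updated variance (scalar).
#' @export
updateVariance <- function(Equad, m, tau = 0, omega = 0) {
  max((Equad + omega) / (m + 2 + tau), SIGMA2_FLOOR)
}

#' Weighted generalized least squares update of the fixed effects
#'
#' @param X fixed design (may have zero columns).
#' @param w pseudo-data weights.
#' @param r residual after removing all random-effect terms from the
#'   working response.
#' @return fixed-effect vector (length ncol(X)).
#' @export
updateBeta <- function(X, w, r) {
  if (ncol(X) == 0L) return(numeric(0))
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("fixed design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  drop(qr.coef(qrX, sqrt(w) * r))
}

#' Damped Newton-Raphson update of the thresholds
#'
#' One or more Newton steps on the exact ordinal log-likelihood in the
#' thresholds, holding the linear predictor fixed. Steps are halved until
#' the log-likelihood does not decrease and the strict ordering
#' t_1 < ... < t_{C-1} is preserved; if no admissible step exists the
#' previous thresholds are kept.
#'
#' @param y integer categories.
#' @param eta linear predictors.
#' @param th current thresholds.
#' @param maxSteps Newton iterations per call (default 5).
#' @return list with `th` and logical `updated`.
#' @export
updateThresholds <- function(y, eta, th, maxSteps = 5L) {
  updated <- FALSE
  for (s in seq_len(maxSteps)) {
    ll0 <- ordinalLoglik(y, eta, th)
    grad <- .thresholdGradient(y, eta, th)
    H <- .thresholdHessian(y, eta, th)
    # ascent direction: -H^-1 g (H negative definite near the optimum),
    # scaled gradient if the solve fails
    step <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) || sum(step * grad) <= 0)
      step <- grad / max(sum(abs(diag(H))), 1)
    ok <- FALSE
    for (h in 0:30) {
      cand <- th + step / 2^h
      if (any(diff(cand) <= 0)) next
      if (ordinalLoglik(y, eta, cand) >= ll0) { ok <- TRUE; break }
    }
    if (!ok) break
    th <- cand
    updated <- TRUE
    if (max(abs(step / 2^h)) < 1e-10) break
  }
  list(th = th, updated = updated)
}

.linearPredictor <- function(design, beta, gamma) {
  eta <- if (ncol(design@X)) drop(design@X %*% beta) else
    numeric(length(design@y))
  for (k in seq_along(design@Z))
    eta <- eta + drop(design@Z[[k]] %*% gamma[[k]])
  eta
}

#' Fit the hierarchical liability model by EM empirical Bayes
#'
#' Initializes effects at zero, fixed effects from seeded uniform draws (or
#' zero), thresholds from the observed phenotype frequencies and block
#' variances from seeded gamma draws, then cycles: rebuild the pseudo-data
#' at the current linear predictor; update every effect block (main-effect
#' blocks in genome order, then QE blocks); update the block variances;
#' update the thresholds; update the fixed effects. Stops when the maximum
#' absolute change over (beta, all gamma, thresholds) falls below
#' `convergenceTol` or at `maxIter` (with a warning and `converged =
#' FALSE`). Two runs with the same `rngSeed` are identical.
#'
#' @param design a [DesignBlocks-class].
#' @param config a [ModelConfig-class].
#' @return an [EBFit-class]
#' @export
ebFit <- function(design, config = modelConfig()) {
  y <- design@y
  n <- length(y)
  nb <- length(design@Z)
  if (!is.na(config@rngSeed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(config@rngSeed)
  }
  beta <- if (config@betaInit == "uniform")
    runif(ncol(design@X), -0.1, 0.1) else numeric(ncol(design@X))
  gamma <- lapply(design@Z, function(Zk) numeric(ncol(Zk)))
  sigma2 <- rgamma(nb, shape = 1, rate = 1) + 0.01
  freqs <- tabulate(y, nbins = design@nCategories)
  if (any(freqs[c(1L, design@nCategories)] == 0L))
    stop("empty first or last category; reduce nCategories")
  freqs[freqs == 0L] <- 0.5  # empty interior category: half-count pad
  th <- thresholdsFromFrequencies(freqs)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(config@maxIter)) {
    eta <- .linearPredictor(design, beta, gamma)
    trace <- c(trace, ordinalLoglik(y, eta, th))
    pd <- pseudoData(y, eta, th, floor = config@weightFloor)
    old <- c(beta, unlist(gamma), th)

    # step 2: effect blocks on partial residuals; step 3: variances
    fitted <- .linearPredictor(design, beta, gamma)
    resid <- pd$ystar - fitted
    Equad <- numeric(nb)
    for (k in seq_len(nb)) {
      rk <- resid + drop(design@Z[[k]] %*% gamma[[k]])
      up <- updateEffectBlock(design@Z[[k]], pd$w, rk, sigma2[k])
      resid <- rk - drop(design@Z[[k]] %*% up$gamma)
      gamma[[k]] <- up$gamma
      Equad[k] <- up$Equad
    }
    for (k in seq_len(nb))
      sigma2[k] <- updateVariance(Equad[k], design@blocks$ncol[k],
                                  config@tau, config@omega)

    # step 4: thresholds at the refreshed predictor
    etaNew <- .linearPredictor(design, beta, gamma)
    th <- updateThresholds(y, etaNew, th)$th

    # step 5: fixed effects
    if (ncol(design@X)) {
      rBeta <- pd$ystar - (etaNew - drop(design@X %*% beta))
      beta <- updateBeta(design@X, pd$w, rBeta)
    }

    delta <- max(abs(c(beta, unlist(gamma), th) - old))
    if (delta < config@convergenceTol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM empirical Bayes fit did not converge in ",
            config@maxIter, " iterations")
  eta <- .linearPredictor(design, beta, gamma)
  trace <- c(trace, ordinalLoglik(y, eta, th))
  new("EBFit", beta = beta, gamma = gamma, sigma2 = sigma2,
      thresholds = th, iterations = iter, converged = converged,
      loglikTrace = trace, design = design, config = config)
}

# Normal-trait analogue of ebFit: identical block/variance/fixed-effect
# machinery applied to an observed continuous response with unit residual
# variance (no link, no thresholds). Used to study the large-C behaviour
# of the ordinal fit.
.normalEbFit <- function(design, yCont, config = modelConfig()) {
  nb <- length(design@Z)
  beta <- numeric(ncol(design@X))
  gamma <- lapply(design@Z, function(Zk) numeric(ncol(Zk)))
  sigma2 <- rep(1, nb)
  w <- rep(1, length(yCont))
  for (iter in seq_len(config@maxIter)) {
    old <- c(beta, unlist(gamma))
    fitted <- .linearPredictor(design, beta, gamma)
    resid <- yCont - fitted
    for (k in seq_len(nb)) {
      rk <- resid + drop(design@Z[[k]] %*% gamma[[k]])
      up <- updateEffectBlock(design@Z[[k]], w, rk, sigma2[k])
      resid <- rk - drop(design@Z[[k]] %*% up$gamma)
      gamma[[k]] <- up$gamma
      sigma2[k] <- updateVariance(up$Equad, design@blocks$ncol[k],
                                  config@tau, config@omega)
    }
    if (ncol(design@X)) {
      rBeta <- yCont - (.linearPredictor(design, beta, gamma) -
                          drop(design@X %*% beta))
      beta <- updateBeta(design@X, w, rBeta)
    }
    if (max(abs(c(beta, unlist(gamma)) - old)) < config@convergenceTol)
      break
  }
  list(beta = beta, gamma = gamma, sigma2 = sigma2)
}
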