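# Probit threshold (liability) likelihood and its pseudo-data normal
# approximation. The residual liability variance is fixed at 1 throughout:
# the liability is unobservable, so its scale is not identifiable.

PROB_FLOOR <- 1e-300

.checkThresholds <- function(th) {
  if (!length(th) || any(!is.finite(th)))
    stop("thresholds must be finite")
  if (length(th) > 1L && any(diff(th) <= 0))
    stop("thresholds must be strictly increasing")
  invisible(th)
}

#' Category probabilities of the probit threshold model
#'
#' With liability u ~ N(eta, 1) and cut points t_1 < ... < t_{C-1}
#' (t_0 = -Inf, t_C = +Inf), category c is observed when u falls in
#' (t_{c-1}, t_c], so P(c) = pnorm(t_c - eta) - pnorm(t_{c-1} - eta).
#'
#' @param eta numeric vector of liability-scale linear predictors.
#' @param th strictly increasing threshold vector of length C-1.
#' @return matrix length(eta) x C of probabilities; rows sum to 1.
#' @examples
#' categoryProbabilities(0, c(-1.2816, -0.5244, 0.5244, 1.2816))
#' @export
categoryProbabilities <- function(eta, th) {
  .checkThresholds(th)
  cuts <- c(-Inf, th, Inf)
  p <- vapply(seq_len(length(cuts) - 1L),
              function(c) pnorm(cuts[c + 1L] - eta) - pnorm(cuts[c] - eta),
              numeric(length(eta)))
  p <- matrix(p, nrow = length(eta))
  colnames(p) <- seq_len(ncol(p))
  p
}

#' Exact ordinal log-likelihood
#'
#' Sum over observations of the log category probability, with a 1e-300
#' probability floor for log safety in extreme tails.
#'
#' @param y integer categories in 1..C.
#' @param eta linear predictors, same length as `y`.
#' @param th thresholds (length C-1).
#' @return scalar log-likelihood.
#' @export
ordinalLoglik <- function(y, eta, th) {
  if (length(y) != length(eta))
    stop("y and eta must have the same length")
  .checkThresholds(th)
  cuts <- c(-Inf, th, Inf)
  p <- pnorm(cuts[y + 1L] - eta) - pnorm(cuts[y] - eta)
  sum(log(pmax(p, PROB_FLOOR)))
}

#' Pseudo-data normal approximation of the ordinal likelihood
#'
#' Local quadratic expansion of each observation's log category probability
#' in the linear predictor (Wolfinger-O'Connell style linearization): the
#' score g_j and curvature w_j yield a working response
#' ystar_j = eta_j + g_j / w_j with weight w_j, so that one step of the
#' mixed-model machinery on (ystar, w) is one Fisher-scoring step on the
#' ordinal likelihood. The observed information is used where positive and
#' replaced by the expected information otherwise, then floored.
#'
#' @param y integer categories.
#' @param eta linear predictors.
#' @param th thresholds.
#' @param floor lower bound on the weights (default 1e-8).
#' @return list with components `ystar`, `w`, `eta`.
#' @export
pseudoData <- function(y, eta, th, floor = 1e-8) {
  if (length(y) != length(eta))
    stop("y and eta must have the same length")
  .checkThresholds(th)
  cuts <- c(-Inf, th, Inf)
  a <- cuts[y] - eta        # lower cut minus eta
  b <- cuts[y + 1L] - eta   # upper cut minus eta
  phiA <- dnorm(a); phiB <- dnorm(b)   # dnorm(+-Inf) = 0
  p <- pmax(pnorm(b) - pnorm(a), PROB_FLOOR)
  g <- (phiA - phiB) / p
  # x * dnorm(x) -> 0 in both tails
  aphiA <- ifelse(is.finite(a), a * phiA, 0)
  bphiB <- ifelse(is.finite(b), b * phiB, 0)
  wObs <- g^2 - (aphiA - bphiB) / p
  # expected information: sum_c (dp_c/deta)^2 / p_c at this eta
  needEI <- which(!(wObs > 0) | !is.finite(wObs))
  if (length(needEI)) {
    C <- length(th) + 1L
    for (j in needEI) {
      lo <- cuts[seq_len(C)] - eta[j]
      hi <- cuts[seq_len(C) + 1L] - eta[j]
      pc <- pmax(pnorm(hi) - pnorm(lo), PROB_FLOOR)
      dpc <- dnorm(lo) - dnorm(hi)
      wObs[j] <- sum(dpc^2 / pc)
    }
  }
  w <- pmax(wObs, floor)
  list(ystar = eta + g / w, w = w, eta = eta)
}

#' Thresholds from target category frequencies
#'
#' Standard-normal quantiles of the cumulative category proportions:
#' t_c = qnorm(F_c), the thresholds under which a N(0,1) liability yields
#' the given marginal category frequencies.
#'
#' @param freqs nonnegative category weights (length C >= 2, sum > 0).
#' @return numeric vector of C-1 strictly increasing thresholds.
#' @examples
#' thresholdsFromFrequencies(c(1, 2, 4, 2, 1))  # -1.2816 ... 1.2816
#' @export
thresholdsFromFrequencies <- function(freqs) {
  if (length(freqs) < 2L) stop("need at least 2 categories")
  if (any(freqs < 0) || sum(freqs) <= 0)
    stop("freqs must be nonnegative with positive sum")
  cum <- cumsum(freqs)[-length(freqs)] / sum(freqs)
  th <- qnorm(cum)
  if (any(!is.finite(th)))
    stop("zero-weight leading/trailing categories make a threshold infinite")
  if (length(th) > 1L && any(diff(th) <= 0))
    stop("zero-weight interior categories produce tied thresholds")
  th
}

# Analytic gradient of the ordinal log-likelihood with respect to the
# thresholds, holding eta fixed. Returns a length C-1 vector.
.thresholdGradient <- function(y, eta, th) {
  cuts <- c(-Inf, th, Inf)
  a <- cuts[y] - eta
  b <- cuts[y + 1L] - eta
  p <- pmax(pnorm(b) - pnorm(a), PROB_FLOOR)
  C1 <- length(th)
  grad <- numeric(C1)
  upper <- dnorm(b) / p   # d logp / d t_{y}   (b = t_y - eta), y < C
  lower <- dnorm(a) / p   # -d logp / d t_{y-1}
  for (c in seq_len(C1)) {
    grad[c] <- sum(upper[y == c]) - sum(lower[y == c + 1L])
  }
  grad
}

# Analytic Hessian (tri-diagonal, (C-1) x (C-1)) of the ordinal
# log-likelihood in the thresholds at fixed eta. An observation in
# category c touches cuts t_{c-1} and t_c only.
.thresholdHessian <- function(y, eta, th) {
  cuts <- c(-Inf, th, Inf)
  a <- cuts[y] - eta
  b <- cuts[y + 1L] - eta
  p <- pmax(pnorm(b) - pnorm(a), PROB_FLOOR)
  phiA <- dnorm(a); phiB <- dnorm(b)
  bphiB <- ifelse(is.finite(b), b * phiB, 0)
  aphiA <- ifelse(is.finite(a), a * phiA, 0)
  C1 <- length(th)
  H <- matrix(0, C1, C1)
  for (c in seq_len(C1 + 1L)) {
    j <- which(y == c)
    if (!length(j)) next
    if (c <= C1)   # upper cut t_c exists
      H[c, c] <- H[c, c] + sum(-bphiB[j] / p[j] - (phiB[j] / p[j])^2)
    if (c >= 2L)   # lower cut t_{c-1} exists
      H[c - 1L, c - 1L] <- H[c - 1L, c - 1L] +
        sum(aphiA[j] / p[j] - (phiA[j] / p[j])^2)
    if (c >= 2L && c <= C1) {
      off <- sum(phiA[j] * phiB[j] / p[j]^2)
      H[c, c - 1L] <- H[c, c - 1L] + off
      H[c - 1L, c] <- H[c - 1L, c] + off
    }
  }
  H
}
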