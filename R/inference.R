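# Two-stage QTL declaration, variance-explained reporting, elite-allele
# mining, best-cross prediction and contingency chi-square tests.

#' Stage-1 selection of effect blocks
#'
#' A block enters the second stage when the largest absolute estimated
#' effect among its alleles exceeds the threshold. Raising the threshold
#' never adds a block.
#'
#' @param fit an [EBFit-class].
#' @param threshold minimum absolute effect (liability scale); defaults to
#'   the fit's `stage1Threshold`.
#' @return data.frame with columns `block`, `locus`, `type`,
#'   `maxAbsEffect`, ordered by block index.
#' @export
stage1Select <- function(fit, threshold = NULL) {
  if (is.null(threshold)) threshold <- fit@config@stage1Threshold
  maxEff <- vapply(fit@gamma, function(g) max(abs(g)), numeric(1))
  keep <- which(maxEff > threshold)
  data.frame(block = keep,
             locus = fit@design@blocks$locus[keep],
             type = fit@design@blocks$type[keep],
             maxAbsEffect = maxEff[keep])
}

#' Proportion of liability variance explained by one block
#'
#' PVE_k = 100 * Var(Z_k gamma_k) / (sum_l Var(Z_l gamma_l) + 1): the
#' sample variance of the block's fitted contribution over observation
#' rows, against total fitted genetic variance plus the unit residual
#' liability variance.
#'
#' @param fit an [EBFit-class].
#' @param block block index.
#' @return percent in \[0, 100\].
#' @export
pve <- function(fit, block) {
  vars <- vapply(seq_along(fit@gamma), function(k)
    var(drop(fit@design@Z[[k]] %*% fit@gamma[[k]])), numeric(1))
  100 * vars[block] / (sum(vars) + 1)
}

#' Mine the elite allele of each declared QTL
#'
#' The elite allele is the known allele with the most favorable estimated
#' effect: the minimum for traits where a smaller grade is better (the
#' default, as with tolerance indices), the maximum otherwise. For a QE
#' call the elite unit is an allele-by-environment pair. Ties are broken
#' toward the allele with more carriers. A representative carrier (first
#' in panel order) is reported along with the full carrier list.
#'
#' @param effects named numeric vector of per-allele effects (names are
#'   allele labels, or "allele x environment" labels for QE blocks).
#' @param panel a [GenotypePanel-class].
#' @param locus the locus name.
#' @param orientation "minimize" or "maximize".
#' @return list with `allele`, `effect`, `carrier`, `carriers`.
#' @export
eliteAlleles <- function(effects, panel, locus,
                         orientation = c("minimize", "maximize")) {
  orientation <- match.arg(orientation)
  stopifnot(length(effects) >= 1L)
  target <- if (orientation == "minimize") min(effects) else max(effects)
  cand <- names(effects)[effects == target]
  g <- alleleMatrix(panel)[, locus]
  alleleLab <- function(lab) sub("x.*$", "", lab)  # QE label -> allele
  if (length(cand) > 1L) {
    nCarr <- vapply(cand, function(lab)
      sum(!is.na(g) & g == alleleLab(lab)), numeric(1))
    cand <- cand[which.max(nCarr)]
  }
  elite <- cand[1L]
  carriers <- cultivarNames(panel)[!is.na(g) & g == alleleLab(elite)]
  if (!length(carriers))
    stop("no carrier found for elite allele ", elite, " at ", locus)
  list(allele = elite, effect = unname(effects[elite]),
       carrier = carriers[1L], carriers = carriers)
}

#' Predict the best parental combinations from detected QTL
#'
#' For every candidate set of 2 to 4 parents, the best achievable
#' recombinant inbred line fixes, at each detected locus, the most
#' favorable allele present among the parents; the cross score is the sum
#' of those allele effects. Crosses are ranked by score (ascending when
#' minimizing) and flagged when they pyramid every elite allele.
#'
#' @param alleleEffects named list per detected locus of per-allele effect
#'   vectors (names are allele labels).
#' @param panel a [GenotypePanel-class].
#' @param parentsPerCross parents per combination, 2..4.
#' @param orientation "minimize" or "maximize".
#' @param candidates optional subset of cultivar ids to enumerate over.
#' @return data.frame of crosses with `score` and `pyramidsAllElite`,
#'   best first.
#' @export
predictBestCross <- function(alleleEffects, panel, parentsPerCross = 2L,
                             orientation = c("minimize", "maximize"),
                             candidates = NULL) {
  orientation <- match.arg(orientation)
  if (parentsPerCross < 2L || parentsPerCross > 4L)
    stop("parentsPerCross must be between 2 and 4")
  if (is.null(candidates)) candidates <- cultivarNames(panel)
  loci <- names(alleleEffects)
  am <- alleleMatrix(panel)[candidates, loci, drop = FALSE]
  best <- function(eff) if (orientation == "minimize") min(eff) else
    max(eff)
  elite <- vapply(alleleEffects, function(eff)
    names(eff)[if (orientation == "minimize") which.min(eff) else
      which.max(eff)], character(1))
  sets <- combn(candidates, parentsPerCross)
  score <- numeric(ncol(sets))
  pyramids <- logical(ncol(sets))
  for (i in seq_len(ncol(sets))) {
    rows <- am[sets[, i], , drop = FALSE]
    s <- 0
    pyr <- TRUE
    for (j in seq_along(loci)) {
      have <- unique(rows[, j])
      have <- have[!is.na(have)]
      eff <- alleleEffects[[j]][names(alleleEffects[[j]]) %in% have]
      if (length(eff)) s <- s + best(eff)
      pyr <- pyr && (elite[j] %in% have)
    }
    score[i] <- s
    pyramids[i] <- pyr
  }
  out <- data.frame(t(sets), score = score, pyramidsAllElite = pyramids)
  names(out)[seq_len(parentsPerCross)] <-
    paste0("parent", seq_len(parentsPerCross))
  out[order(if (orientation == "minimize") score else -score), ,
      drop = FALSE]
}

#' Pearson chi-square test of independence
#'
#' Wraps the Pearson test (no continuity correction) after dropping
#' zero-margin rows and columns with a warning.
#'
#' @param tab 2-D contingency table of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chisqIndependence <- function(tab) {
  tab <- as.matrix(tab)
  if (all(tab == 0)) stop("all-zero contingency table")
  keepR <- rowSums(tab) > 0
  keepC <- colSums(tab) > 0
  if (!all(keepR) || !all(keepC)) {
    warning("dropping zero-margin row(s)/column(s)")
    tab <- tab[keepR, keepC, drop = FALSE]
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Map ordinal-trait QTL in a cultivar panel
#'
#' The full pipeline: build the design, fit the hierarchical liability
#' model by EM empirical Bayes, select blocks whose largest absolute
#' allelic effect passes the stage-1 threshold, confirm each by a
#' likelihood-ratio test on the exact ordinal likelihood (LOD =
#' LR / (2 ln 10)), and report declared QTL with PVE, elite alleles and
#' carriers.
#'
#' @param panel a [GenotypePanel-class].
#' @param phen an [OrdinalPhenotypes-class].
#' @param q optional [StructureCovariates-class].
#' @param config a [ModelConfig-class].
#' @param orientation elite-allele orientation, "minimize" (default) or
#'   "maximize".
#' @return an [OrdinalQtlResult-class]
#' @export
mapOrdinalQtl <- function(panel, phen, q = NULL, config = modelConfig(),
                          orientation = c("minimize", "maximize")) {
  orientation <- match.arg(orientation)
  design <- buildDesign(panel, phen, q, config)
  fit <- ebFit(design, config)
  selected <- stage1Select(fit)
  map <- markerMap(panel)
  calls <- data.frame()
  alleleEffects <- list()
  carriers <- list()
  for (i in seq_len(nrow(selected))) {
    k <- selected$block[i]
    lr <- tryCatch(lrtLocus(design, selected$block, k),
                   error = function(e) {
                     warning("LRT failed for block ", k, ": ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(lr) || lr$LOD < config@lodThreshold) next
    loc <- design@blocks$locus[k]
    eff <- setNames(fit@gamma[[k]], design@alleleLevels[[k]])
    el <- eliteAlleles(eff, panel, loc, orientation)
    mrow <- map[map$locus == loc, ]
    callName <- paste0(loc, if (design@blocks$type[k] == "QE") ":QE")
    calls <- rbind(calls, data.frame(
      qtl = callName, locus = loc, type = design@blocks$type[k],
      chromosome = mrow$chromosome[1], position_cM = mrow$position_cM[1],
      sigma2 = fit@sigma2[k],
      varFitted = var(drop(design@Z[[k]] %*% fit@gamma[[k]])),
      LR = lr$LR, LOD = lr$LOD, PVE = pve(fit, k),
      eliteAllele = el$allele, eliteEffect = el$effect,
      carrier = el$carrier))
    alleleEffects[[callName]] <- eff
    carriers[[callName]] <- el$carriers
  }
  rownames(calls) <- NULL
  new("OrdinalQtlResult", calls = calls, alleleEffects = alleleEffects,
      carriers = carriers, selected = selected, fit = fit)
}

#' Write the fit report
#'
#' Emits the declared-QTL table as CSV and the full result (calls,
#' per-allele effects, carriers, thresholds, block variances, convergence
#' trace) as JSON.
#'
#' @param result an [OrdinalQtlResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFitReport <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "qtl_calls.csv")
  write.table(qtlCalls(result), csv, sep = ",", row.names = FALSE,
              quote = FALSE)
  fit <- result@fit
  js <- file.path(dir, "fit_report.json")
  jsonlite::write_json(list(
    calls = qtlCalls(result),
    alleleEffects = lapply(result@alleleEffects, as.list),
    carriers = result@carriers,
    thresholds = fit@thresholds,
    beta = fit@beta,
    sigma2 = unname(fit@sigma2),
    iterations = fit@iterations,
    converged = fit@converged,
    loglikTrace = fit@loglikTrace,
    rngSeed = fit@config@rngSeed
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
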