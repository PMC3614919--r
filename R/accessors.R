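#' @rdname GenotypePanel-class
#' @aliases cultivarNames,GenotypePanel-method
setMethod("cultivarNames", "GenotypePanel",
          function(x) rownames(x@alleles))

#' @rdname GenotypePanel-class
setMethod("lociNames", "GenotypePanel", function(x) colnames(x@alleles))

#' @rdname GenotypePanel-class
setMethod("alleleMatrix", "GenotypePanel", function(x) x@alleles)

#' @rdname GenotypePanel-class
setMethod("markerMap", "GenotypePanel", function(x) x@map)

#' @rdname knownAlleles
setMethod("knownAlleles", "GenotypePanel", function(x) {
  apply(x@alleles, 2, function(a) sort(unique(a[!is.na(a)])),
        simplify = FALSE)
})

#' @rdname OrdinalPhenotypes-class
setMethod("phenoTable", "OrdinalPhenotypes", function(x) x@data)

#' @rdname OrdinalPhenotypes-class
setMethod("nCategories", "OrdinalPhenotypes", function(x) x@nCategories)

setMethod("nCategories", "DesignBlocks", function(x) x@nCategories)

#' @rdname EBFit-class
#' @param x an EBFit
setMethod("thresholds", "EBFit", function(x) x@thresholds)

#' @rdname EBFit-class
setMethod("blockVariances", "EBFit", function(x) {
  setNames(x@sigma2, paste(x@design@blocks$locus, x@design@blocks$type,
                           sep = ":"))
})

#' @rdname EBFit-class
setMethod("blockEffects", "EBFit", function(x) {
  setNames(x@gamma, paste(x@design@blocks$locus, x@design@blocks$type,
                          sep = ":"))
})

#' @rdname OrdinalQtlResult-class
setMethod("qtlCalls", "OrdinalQtlResult", function(x) x@calls)

setMethod("thresholds", "OrdinalQtlResult", function(x) x@fit@thresholds)

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@alleles), "cultivars x",
      ncol(object@alleles), "loci\n")
  ka <- lengths(knownAlleles(object))
  if (length(ka))
    cat("  known alleles per locus:", min(ka), "-", max(ka), "\n")
  nmiss <- sum(is.na(object@alleles))
  cat("  unknown genotypes:", nmiss, "\n")
})

setMethod("show", "OrdinalPhenotypes", function(object) {
  d <- object@data
  cat("OrdinalPhenotypes:", nrow(d), "records,",
      length(unique(d$cultivar)), "cultivars,",
      length(unique(d$environment)), "environment(s),",
      object@nCategories, "categories\n")
  print(table(category = d$category))
})

setMethod("show", "DesignBlocks", function(object) {
  cat("DesignBlocks:", length(object@y), "observations,",
      ncol(object@X), "fixed column(s),", length(object@Z),
      "random block(s)\n")
  cat("  MQ blocks:", sum(object@blocks$type == "MQ"),
      " QE blocks:", sum(object@blocks$type == "QE"), "\n")
})

setMethod("show", "EBFit", function(object) {
  cat("EBFit:", if (object@converged) "converged" else "NOT converged",
      "after", object@iterations, "iterations\n")
  cat("  log-likelihood:",
      format(object@loglikTrace[length(object@loglikTrace)], digits = 6),
      "\n  thresholds:",
      paste(format(object@thresholds, digits = 4), collapse = ", "), "\n")
})

setMethod("show", "OrdinalQtlResult", function(object) {
  cat("OrdinalQtlResult:", nrow(object@calls), "QTL declared (",
      sum(object@calls$type == "MQ"), "MQ,",
      sum(object@calls$type == "QE"), "QE )\n")
  if (nrow(object@calls)) print(object@calls, row.names = FALSE)
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", object@nFounders, "founders,",
      object@nNonfounders, "non-founders,",
      nrow(object@chromosomes), "chromosome(s),",
      nrow(object@qtl), "QTL,",
      length(object@categoryFreqs), "categories\n")
})

setMethod("show", "PowerResult", function(object) {
  cat("PowerResult over", object@power$replicates[1], "replicates",
      "(", object@excluded, "excluded )\n")
  print(object@power, row.names = FALSE)
  cat("  FPR:", format(object@fpr, digits = 4), "\n")
})
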