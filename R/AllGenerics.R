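#' @rdname GenotypePanel-class
#' @param object,x an object
#' @export
setGeneric("cultivarNames", function(x) standardGeneric("cultivarNames"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' Known alleles at each locus
#'
#' Sorted unique non-missing allele labels per locus; unknown genotypes are
#' never counted.
#' @param x a [GenotypePanel-class]
#' @return named list of character vectors
#' @export
setGeneric("knownAlleles", function(x) standardGeneric("knownAlleles"))

#' @rdname OrdinalPhenotypes-class
#' @export
setGeneric("phenoTable", function(x) standardGeneric("phenoTable"))

#' @rdname OrdinalPhenotypes-class
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' Estimated liability thresholds
#' @param x a fitted object
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' Per-block variance estimates
#' @param x a fitted object
#' @export
setGeneric("blockVariances", function(x) standardGeneric("blockVariances"))

#' Per-block effect estimates
#' @param x a fitted object
#' @export
setGeneric("blockEffects", function(x) standardGeneric("blockEffects"))

#' Declared QTL table
#' @param x an [OrdinalQtlResult-class]
#' @export
setGeneric("qtlCalls", function(x) standardGeneric("qtlCalls"))
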