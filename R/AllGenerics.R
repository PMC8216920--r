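#' Number of individuals in a genotype table
#' @param x a GenotypeTable
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' Locus names
#' @param x a GenotypeTable or AlleleFreqTable
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Individual metadata accessor
#' @param x a GenotypeTable
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' Allele-frequency list accessor
#' @param x an AlleleFreqTable
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))

#' Long-format relatedness estimates accessor
#' @param x a RelatednessMatrix
#' @export
setGeneric("estimates", function(x) standardGeneric("estimates"))
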