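# Genotype data model: accessors, filtering, allele frequencies, diversity.

#' @describeIn GenotypeTable number of individuals
#' @param x a GenotypeTable
#' @export
setMethod("nInd", "GenotypeTable", function(x) nrow(x@a1))

#' @describeIn GenotypeTable locus names
#' @export
setMethod("lociNames", "GenotypeTable", function(x) colnames(x@a1))

#' @describeIn GenotypeTable per-individual metadata data.frame
#' @export
setMethod("individuals", "GenotypeTable", function(x) x@meta)

#' @describeIn AlleleFreqTable locus names
#' @param x an AlleleFreqTable
#' @export
setMethod("lociNames", "AlleleFreqTable", function(x) names(x@freqs))

#' @describeIn AlleleFreqTable named list of per-locus frequency vectors
#' @export
setMethod("alleleFreqs", "AlleleFreqTable", function(x) x@freqs)

#' Subset a GenotypeTable by individuals (rows) and loci (columns)
#'
#' @param x GenotypeTable
#' @param i individual ids, indices or logical vector
#' @param j locus names, indices or logical vector
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(ncol(x@a1))
  if (is.character(i)) i <- match(i, x@meta$id)
  if (anyNA(i)) stop("unknown individual id in subset")
  new("GenotypeTable",
      a1 = x@a1[i, j, drop = FALSE], a2 = x@a2[i, j, drop = FALSE],
      meta = x@meta[i, , drop = FALSE])
})

setMethod("show", "GenotypeTable", function(object) {
  m <- object@meta
  cat(sprintf("GenotypeTable: %d individuals x %d loci\n",
              nInd(object), ncol(object@a1)))
  if (nInd(object)) {
    cat(sprintf("  sex: %s\n",
                paste(sprintf("%s=%d", names(table(m$sex)), table(m$sex)),
                      collapse = ", ")))
    grp <- table(m$group, useNA = "ifany")
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
    miss <- mean(is.na(object@a1))
    cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  }
  invisible(object)
})

setMethod("show", "AlleleFreqTable", function(object) {
  k <- vapply(object@freqs, length, 1L)
  cat(sprintf("AlleleFreqTable: %d loci, %.1f alleles/locus (reference: %s)\n",
              length(k), mean(k), object@referenceSet))
  invisible(object)
})

setMethod("show", "RelatednessMatrix", function(object) {
  e <- object@estimates
  cat(sprintf("RelatednessMatrix (%s): %d individuals, %d pairs (%d undefined)\n",
              object@estimator, length(object@ids), nrow(e),
              sum(is.na(e$value))))
  invisible(object)
})

#' Coerce a RelatednessMatrix to a square symmetric matrix
#'
#' @param x RelatednessMatrix
#' @param ... ignored
#' @return numeric matrix with NA diagonal; undefined pairs are NA.
#' @export
as.matrix.RelatednessMatrix <- function(x, ...) {
  ids <- x@ids
  M <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  e <- x@estimates
  M[cbind(e$id1, e$id2)] <- e$value
  M[cbind(e$id2, e$id1)] <- e$value
  M
}
setMethod("estimates", "RelatednessMatrix", function(x) x@estimates)

#' Count non-missing loci per individual
#' @param table GenotypeTable
#' @return named integer vector
#' @export
validLociCount <- function(table) {
  n <- rowSums(!is.na(table@a1))
  names(n) <- table@meta$id
  n
}

#' Drop individuals typed at too few loci
#'
#' Retains exactly the individuals with at least \code{minValidLoci}
#' non-missing loci.  The default of 7 implements a "more than six valid
#' markers" inclusion rule for a ten-locus panel.  Removed ids are reported
#' via \code{message()} and attached as attribute \code{"removed"}.
#'
#' @param table GenotypeTable
#' @param minValidLoci minimum number of successfully typed loci (>= 0)
#' @return filtered GenotypeTable (idempotent)
#' @export
filterIndividuals <- function(table, minValidLoci = 7) {
  stopifnot(minValidLoci >= 0)
  n <- validLociCount(table)
  keep <- n >= minValidLoci
  removed <- names(n)[!keep]
  if (length(removed))
    message("filterIndividuals: removed ", length(removed), " individual(s): ",
            paste(removed, collapse = ", "))
  out <- table[which(keep), ]
  if (nInd(out) == 0) warning("all individuals removed by locus filter")
  attr(out, "removed") <- removed
  out
}

#' Estimate per-locus allele frequencies by direct counting
#'
#' Counts observed allele copies per locus over a reference subset of
#' individuals and normalises to 1.  The reference defaults to all
#' successfully typed individuals; a predicate over the metadata rows (for
#' example adults only) restricts it.
#'
#' @param table GenotypeTable
#' @param referenceFilter optional function taking the metadata data.frame
#'   and returning a logical vector of individuals to use
#' @param referenceSet optional character label describing the reference
#' @return \linkS4class{AlleleFreqTable}
#' @export
alleleFrequencies <- function(table, referenceFilter = NULL,
                              referenceSet = NULL) {
  meta <- table@meta
  keep <- if (is.null(referenceFilter)) rep(TRUE, nrow(meta))
          else referenceFilter(meta)
  if (!any(keep)) stop("reference subset is empty")
  a1 <- table@a1[keep, , drop = FALSE]
  a2 <- table@a2[keep, , drop = FALSE]
  loci <- colnames(a1)
  freqs <- vector("list", length(loci)); names(freqs) <- loci
  nGenes <- numeric(length(loci)); names(nGenes) <- loci
  for (l in loci) {
    alleles <- c(a1[, l], a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles))
      stop("locus ", l, " has no typed reference individual")
    tab <- table(alleles)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    freqs[[l]] <- f[order(as.integer(names(f)))]
    nGenes[l] <- length(alleles)
  }
  if (is.null(referenceSet))
    referenceSet <- if (is.null(referenceFilter))
      sprintf("all %d typed individuals", sum(keep))
    else sprintf("filtered subset of %d individuals", sum(keep))
  new("AlleleFreqTable", freqs = freqs, nGenes = nGenes,
      referenceSet = referenceSet)
}

#' Construct an AlleleFreqTable from explicit frequency vectors
#'
#' @param freqs list of named numeric vectors (names = allele sizes)
#' @param nGenes typed gene copies per locus; NA (default) marks population
#'   frequencies, disabling finite-sample corrections downstream
#' @param referenceSet provenance label
#' @export
alleleFreqTable <- function(freqs, nGenes = NA_real_,
                            referenceSet = "explicit") {
  if (is.null(names(freqs)))
    names(freqs) <- paste0("L", seq_along(freqs))
  nGenes <- rep_len(nGenes, length(freqs))
  names(nGenes) <- names(freqs)
  new("AlleleFreqTable", freqs = freqs, nGenes = nGenes,
      referenceSet = referenceSet)
}

#' Locus diversity and multilocus probability of identity
#'
#' Per-locus allele counts and expected heterozygosity, their means, and the
#' multilocus probability of identity
#' \deqn{PID = \prod_l [\sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2],}
#' the probability that two random individuals share an identical multilocus
#' genotype under Hardy-Weinberg.  He uses Nei's unbiased correction
#' n/(n-1) * (1 - sum p^2) by default (n = typed gene copies); the raw
#' Gini-Simpson form is selectable, and is also used when the table carries
#' population frequencies (nGenes = NA).
#'
#' @param freqs AlleleFreqTable
#' @param heMode "unbiased" (default) or "raw"
#' @return list of class "DiversitySummary": perLocus data.frame (locus,
#'   nAlleles, He), meanAlleles, meanHe, pid
#' @export
diversitySummary <- function(freqs, heMode = c("unbiased", "raw")) {
  heMode <- match.arg(heMode)
  loci <- lociNames(freqs)
  nAll <- integer(length(loci)); He <- numeric(length(loci))
  pidL <- numeric(length(loci))
  for (i in seq_along(loci)) {
    p <- freqs@freqs[[i]]
    nAll[i] <- length(p)
    he <- 1 - sum(p^2)
    n <- freqs@nGenes[i]
    if (heMode == "unbiased" && is.finite(n) && n > 1)
      he <- he * n / (n - 1)
    He[i] <- he
    # PID at one locus: sum over identical genotype pairs under HWE
    pidL[i] <- sum(p^4) + sum((2 * outer(p, p))[upper.tri(diag(length(p)))]^2)
  }
  out <- list(perLocus = data.frame(locus = loci, nAlleles = nAll, He = He,
                                    pidLocus = pidL),
              meanAlleles = mean(nAll), meanHe = mean(He), pid = prod(pidL),
              heMode = heMode)
  class(out) <- "DiversitySummary"
  out
}

#' @export
print.DiversitySummary <- function(x, ...) {
  cat(sprintf("Diversity over %d loci: mean alleles/locus = %.2f, mean He = %.3f (%s)\n",
              nrow(x$perLocus), x$meanAlleles, x$meanHe, x$heMode))
  cat(sprintf("Multilocus probability of identity: %.3g\n", x$pid))
  invisible(x)
}

#' Write a diversity summary as TSV or JSON
#' @param x DiversitySummary
#' @param path output file; format chosen by extension (.json otherwise TSV)
#' @export
writeDiversitySummary <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(perLocus = x$perLocus, meanAlleles = x$meanAlleles,
           meanHe = x$meanHe, pid = x$pid),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$perLocus, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
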