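#' @import methods
NULL

#' Multilocus codominant genotype table with individual metadata
#'
#' The central data container of the package: two integer allele-size
#' matrices (individuals x loci; for each individual and locus the unordered
#' genotype is stored with the smaller size in \code{a1}) plus a metadata
#' data frame describing each individual.  A genotype is either fully typed
#' (two positive integer allele sizes, homozygotes repeat one size) or
#' missing at the whole-locus level (both entries \code{NA}).
#'
#' Metadata columns: \code{id}, \code{sex} (\code{male}/\code{female}/
#' \code{unknown}), \code{age_class} (\code{adult}/\code{immature}),
#' \code{role} (\code{silverback}, \code{adult_female}, \code{immature},
#' \code{solitary_male}), \code{group} (group label, or \code{NA}; solitary
#' males carry the host group whose home range they use, so they inherit its
#' coordinates), \code{country}.
#'
#' @slot a1 integer matrix of first (smaller) allele sizes, rownames = ids.
#' @slot a2 integer matrix of second allele sizes, same dimnames as a1.
#' @slot meta data.frame of per-individual metadata, one row per individual.
#' @export
setClass("GenotypeTable",
         slots = c(a1 = "matrix", a2 = "matrix", meta = "data.frame"))

.validGenotypeTable <- function(object) {
  msgs <- character()
  a1 <- object@a1; a2 <- object@a2; meta <- object@meta
  if (!identical(dim(a1), dim(a2)))
    msgs <- c(msgs, "a1 and a2 must have identical dimensions")
  if (!identical(dimnames(a1), dimnames(a2)))
    msgs <- c(msgs, "a1 and a2 must have identical dimnames")
  need <- c("id", "sex", "age_class", "role", "group", "country")
  if (!all(need %in% names(meta)))
    msgs <- c(msgs, paste("meta must contain columns:",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(meta$id))
      msgs <- c(msgs, "individual ids must be unique")
    rn <- rownames(a1)
    if (is.null(rn)) rn <- character(0)
    if (!identical(as.character(meta$id), rn))
      msgs <- c(msgs, "rownames(a1) must equal meta$id in order")
    bad_sex <- !meta$sex %in% c("male", "female", "unknown")
    if (any(bad_sex))
      msgs <- c(msgs, "sex must be one of male/female/unknown")
    sb <- meta$role %in% "silverback"
    if (any(sb & (meta$sex != "male" | meta$age_class != "adult")))
      msgs <- c(msgs, "silverbacks must be adult males")
  }
  if (nrow(a1) > 0 && ncol(a1) > 0) {
    na_mismatch <- xor(is.na(a1), is.na(a2))
    if (any(na_mismatch))
      msgs <- c(msgs, "genotypes must be missing at the whole-locus level (both alleles NA)")
    if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
      msgs <- c(msgs, "allele sizes must be strictly positive integers")
    if (any(a1 > a2, na.rm = TRUE))
      msgs <- c(msgs, "a1 must hold the smaller allele of each genotype")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("GenotypeTable", .validGenotypeTable)

#' Construct a GenotypeTable
#'
#' @param a1,a2 numeric matrices of allele sizes (individuals x loci); the
#'   pair at each cell is unordered and is canonicalised so that a1 <= a2.
#' @param meta data.frame with columns id, sex, age_class, role, group,
#'   country (missing columns are filled with sensible defaults).
#' @return A validated \linkS4class{GenotypeTable}.
#' @export
GenotypeTable <- function(a1, a2, meta) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$sex)) meta$sex <- "unknown"
  if (is.null(meta$age_class)) meta$age_class <- "adult"
  if (is.null(meta$role)) meta$role <- NA_character_
  if (is.null(meta$group)) meta$group <- NA_character_
  if (is.null(meta$country)) meta$country <- NA_character_
  meta$id <- as.character(meta$id)
  rownames(lo) <- rownames(hi) <- meta$id
  rownames(meta) <- NULL
  new("GenotypeTable", a1 = lo, a2 = hi,
      meta = meta[c("id", "sex", "age_class", "role", "group", "country")])
}

#' Per-locus allele frequency table
#'
#' Allele frequencies estimated from a stated reference set of individuals.
#' \code{nGenes} records, per locus, the number of typed gene copies
#' (2 x typed individuals) behind the estimate; \code{NA} marks population
#' (true) frequencies for which no finite-sample correction applies.
#'
#' @slot freqs list, one named numeric vector per locus (names = allele
#'   sizes, values sum to 1, all > 0).
#' @slot nGenes numeric vector, typed gene copies per locus (NA = population
#'   frequencies).
#' @slot referenceSet character description of the individuals used.
#' @export
setClass("AlleleFreqTable",
         slots = c(freqs = "list", nGenes = "numeric",
                   referenceSet = "character"))

setValidity("AlleleFreqTable", function(object) {
  msgs <- character()
  if (length(object@freqs) != length(object@nGenes))
    msgs <- c(msgs, "freqs and nGenes must have one entry per locus")
  for (l in names(object@freqs)) {
    f <- object@freqs[[l]]
    if (is.null(names(f)) || any(!is.finite(f)))
      msgs <- c(msgs, sprintf("locus %s: frequencies must be named and finite", l))
    else {
      if (abs(sum(f) - 1) > 1e-9)
        msgs <- c(msgs, sprintf("locus %s: frequencies must sum to 1", l))
      if (any(f <= 0))
        msgs <- c(msgs, sprintf("locus %s: every frequency must be > 0", l))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Pairwise relatedness matrix
#'
#' Long-format store of pairwise relatedness estimates over all unordered
#' pairs of a set of individuals, with the estimator tag and the provenance
#' of the reference allele frequencies.  Pairs with fewer shared typed loci
#' than the minimum are present but carry \code{NA} values (flagged
#' undefined rather than silently dropped).
#'
#' @slot estimates data.frame with columns id1, id2, value, nLoci, p.
#' @slot estimator one of "QG", "LR", "LOISELLE".
#' @slot ids character vector of the individuals covered.
#' @slot reference description of the allele-frequency reference set.
#' @export
setClass("RelatednessMatrix",
         slots = c(estimates = "data.frame", estimator = "character",
                   ids = "character", reference = "character"))

setValidity("RelatednessMatrix", function(object) {
  msgs <- character()
  need <- c("id1", "id2", "value", "nLoci", "p")
  if (!all(need %in% names(object@estimates)))
    msgs <- c(msgs, "estimates needs columns id1,id2,value,nLoci,p")
  else {
    e <- object@estimates
    if (any(e$id1 == e$id2))
      msgs <- c(msgs, "diagonal (self) pairs are excluded")
    key <- paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
    if (anyDuplicated(key))
      msgs <- c(msgs, "each unordered pair may appear once")
  }
  if (!object@estimator %in% c("QG", "LR", "LOISELLE"))
    msgs <- c(msgs, "estimator must be QG, LR or LOISELLE")
  if (length(msgs)) msgs else TRUE
})
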