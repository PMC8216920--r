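# Permutation tests for kin association: within-group / within-country mean
# relatedness, female-to-own-silverback relatedness, and significant-pair
# proportions.
#
# p-value convention throughout: p = (# null values >= observed) / nPerm
# (the one-tailed "excess relatedness" alternative).  The optional
# (+1)/(n+1) correction never returns exactly zero.

.permResult <- function(unit, observed, null, nPerm, seed,
                        plusOne = FALSE) {
  p <- if (plusOne) (sum(null >= observed) + 1) / (nPerm + 1)
       else sum(null >= observed) / nPerm
  structure(list(unit = unit, observed = observed, null = null,
                 p = p, nPerm = nPerm, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Permutation test [%s]: observed mean = %.4f, p = %.4g (%d permutations)\n",
              x$unit, x$observed, x$p, x$nPerm))
  invisible(x)
}

.withinMean <- function(M, idx) {
  if (length(idx) < 2) return(NA_real_)
  v <- M[idx, idx][upper.tri(diag(length(idx)))]
  mean(v, na.rm = TRUE)
}

#' Within-group mean relatedness permutation test
#'
#' Tests, for each group, whether its members are more related on average
#' than random sets of the same size drawn from the whole matrix.  The null
#' reshuffles individuals among groups preserving group sizes; the
#' one-tailed p-value is the fraction of permuted within-group means at or
#' above the observed mean.  Undefined pairs are excluded from both the
#' observed and null means.  Groups of size one are excluded with a
#' warning.
#'
#' @param rmat RelatednessMatrix
#' @param labels named character vector id -> group for the individuals to
#'   test (ids absent from the matrix are an error)
#' @param nPerm number of permutations (default 10000)
#' @param seed optional RNG seed
#' @param plusOne use the (+1)/(n+1) p-value correction
#' @return named list of \code{PermutationResult}, one per tested group
#' @export
groupMeanRelatednessTest <- function(rmat, labels, nPerm = 10000,
                                     seed = NULL, plusOne = FALSE) {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be a named vector (names = ids)")
  if (!all(ids %in% rmat@ids)) stop("labels name ids absent from the matrix")
  groups <- unique(labels)
  if (length(groups) < 2) stop("need at least two groups")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding size-1 group(s): ", paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  if (!length(groups)) stop("no group with at least two members")
  M <- as.matrix(rmat)[ids, ids]
  if (!is.null(seed)) set.seed(seed)
  obs <- vapply(groups, function(g) .withinMean(M, which(labels == g)), 1)
  null <- matrix(NA_real_, nPerm, length(groups),
                 dimnames = list(NULL, groups))
  for (b in seq_len(nPerm)) {
    perm <- sample(labels)
    for (g in groups) null[b, g] <- .withinMean(M, which(perm == g))
  }
  out <- lapply(groups, function(g)
    .permResult(g, obs[g], null[, g], nPerm, seed, plusOne))
  names(out) <- groups
  out
}

#' Female-to-own-silverback relatedness test
#'
#' Observed statistic: the mean relatedness of each female to the breeding
#' male of her own group, averaged over females.  Null: for each female
#' independently, a male is drawn uniformly from the male pool, and the
#' average recomputed; \code{nPerm} replicates.  One-tailed p for excess
#' relatedness; the two-tailed p (doubling the smaller tail) is attached as
#' \code{pTwoSided}.
#'
#' @param rmat RelatednessMatrix
#' @param ownMale named character vector female id -> own male id
#' @param malePool character vector of candidate male ids
#' @param nPerm permutations (default 10000)
#' @param seed optional RNG seed
#' @return PermutationResult with an extra \code{pTwoSided} element
#' @export
focalMaleRelatednessTest <- function(rmat, ownMale, malePool,
                                     nPerm = 10000, seed = NULL) {
  females <- names(ownMale)
  if (is.null(females)) stop("ownMale must be named by female id")
  if (!length(malePool)) stop("empty male pool")
  M <- as.matrix(rmat)
  if (!all(c(females, unname(ownMale), malePool) %in% rownames(M)))
    stop("ids absent from the relatedness matrix")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(M[cbind(females, unname(ownMale))], na.rm = TRUE)
  nf <- length(females)
  draw <- matrix(sample(malePool, nf * nPerm, replace = TRUE), nf, nPerm)
  vals <- matrix(M[cbind(rep(females, nPerm), as.vector(draw))], nf, nPerm)
  null <- colMeans(vals, na.rm = TRUE)
  res <- .permResult("females_vs_own_male", obs, null, nPerm, seed)
  pl <- sum(null <= obs) / nPerm
  res$pTwoSided <- min(1, 2 * min(res$p, pl))
  res
}

#' Within-partition relatedness test after sex filtering
#'
#' Same machinery as \code{\link{groupMeanRelatednessTest}} applied to a
#' coarser partition (typically country/region) after restricting to one
#' sex.
#'
#' @param rmat RelatednessMatrix
#' @param labels named vector id -> partition (e.g. country)
#' @param sex named vector id -> sex
#' @param sexFilter "female" or "male"
#' @inheritParams groupMeanRelatednessTest
#' @return named list of PermutationResult, one per partition
#' @export
partitionRelatednessTest <- function(rmat, labels, sex,
                                     sexFilter = c("female", "male"),
                                     nPerm = 10000, seed = NULL,
                                     plusOne = FALSE) {
  sexFilter <- match.arg(sexFilter)
  keep <- names(labels)[sex[names(labels)] == sexFilter]
  if (length(unique(labels[keep])) < 2)
    stop("need at least two partitions after sex filtering")
  groupMeanRelatednessTest(rmat, labels[keep], nPerm, seed, plusOne)
}

#' Proportions of significantly related pairs within and among units
#'
#' Splits the pairwise p-values of a relatedness matrix by whether the two
#' members share a label, counting pairs with p < alpha.
#'
#' @param rmat RelatednessMatrix carrying per-pair p-values
#' @param labels named vector id -> unit
#' @param alpha significance level (default 0.05)
#' @return list: within (k, n, proportion), among (k, n, proportion)
#' @export
significantPairSummary <- function(rmat, labels, alpha = 0.05) {
  e <- rmat@estimates
  keep <- e$id1 %in% names(labels) & e$id2 %in% names(labels) & !is.na(e$p)
  e <- e[keep, ]
  same <- labels[e$id1] == labels[e$id2]
  sig <- e$p < alpha
  list(within = list(k = sum(sig & same), n = sum(same),
                     proportion = if (sum(same)) mean(sig[same]) else NA_real_),
       among = list(k = sum(sig & !same), n = sum(!same),
                    proportion = if (sum(!same)) mean(sig[!same]) else NA_real_),
       alpha = alpha)
}

#' Export a permutation test result as JSON with a null histogram CSV
#'
#' @param x PermutationResult
#' @param jsonPath JSON output (observed, p, nPerm, seed)
#' @param histPath optional CSV of null-distribution bin counts
#' @param breaks histogram breaks passed to \code{hist}
#' @export
writePermutationResult <- function(x, jsonPath, histPath = NULL,
                                   breaks = 30) {
  jsonlite::write_json(list(unit = x$unit, observed = x$observed, p = x$p,
                            nPerm = x$nPerm,
                            seed = if (is.null(x$seed)) NA else x$seed),
                       jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(histPath)) {
    h <- graphics::hist(x$null, breaks = breaks, plot = FALSE)
    utils::write.csv(data.frame(binStart = h$breaks[-length(h$breaks)],
                                binEnd = h$breaks[-1], count = h$counts),
                     histPath, row.names = FALSE)
  }
  invisible(jsonPath)
}
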