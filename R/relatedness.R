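# Pairwise relatedness: Queller-Goodnight, Lynch-Ritland and Loiselle
# estimators, allele-permutation significance, estimator concordance.
#
# All three are method-of-moment estimators computed against reference
# allele frequencies.  QG and LR are relatedness coefficients (expectation
# 0.5 for parent-offspring/full sibs); Loiselle is a kinship coefficient
# (half those values).

# Vectorised engine: given paired allele matrices (dyads x loci) for the two
# members of each dyad, return the multilocus estimate and shared-locus
# count per dyad.  The per-locus algebra is written against one "reference"
# orientation; QG and LR are symmetrised as the mean of the two
# orientations, Loiselle is symmetric by construction.
.relEngine <- function(xa1, xa2, ya1, ya2, freqs, estimator) {
  loci <- names(alleleFreqs(freqs))
  nd <- nrow(xa1)
  nLoci <- integer(nd)
  if (estimator %in% c("QG", "LR")) {
    numX <- denX <- numY <- denY <- numeric(nd)
    for (l in loci) {
      a <- xa1[, l]; b <- xa2[, l]; cc <- ya1[, l]; d <- ya2[, l]
      ok <- !is.na(a) & !is.na(cc)
      if (!any(ok)) next
      f <- freqs@freqs[[l]]
      sizes <- as.integer(names(f))
      pa <- unname(f[match(a, sizes)]); pb <- unname(f[match(b, sizes)])
      pc <- unname(f[match(cc, sizes)]); pd <- unname(f[match(d, sizes)])
      if (anyNA(pa[ok]) || anyNA(pb[ok]) || anyNA(pc[ok]) || anyNA(pd[ok]))
        stop("observed allele absent from frequency table at locus ", l)
      dac <- (a == cc); dad <- (a == d); dbc <- (b == cc); dbd <- (b == d)
      dab <- (a == b); dcd <- (cc == d)
      S <- dac + dad + dbc + dbd
      if (estimator == "QG") {
        nx <- 0.5 * S - pa - pb;  dx <- 1 + dab - pa - pb
        ny <- 0.5 * S - pc - pd;  dy <- 1 + dcd - pc - pd
      } else {                                     # LR with locus weights
        # per-locus value r_l = nx/dx, weight w_l = dx/(2 pa pb);
        # multilocus = sum(w r)/sum(w) = sum(nx/(2 pa pb)) / sum(w)
        nx0 <- pa * (dbc + dbd) + pb * (dac + dad) - 4 * pa * pb
        dx0 <- (1 + dab) * (pa + pb) - 4 * pa * pb
        ny0 <- pc * (dad + dbd) + pd * (dac + dbc) - 4 * pc * pd
        dy0 <- (1 + dcd) * (pc + pd) - 4 * pc * pd
        nx <- nx0 / (2 * pa * pb); dx <- dx0 / (2 * pa * pb)
        ny <- ny0 / (2 * pc * pd); dy <- dy0 / (2 * pc * pd)
      }
      useX <- ok & is.finite(dx) & dx != 0
      useY <- ok & is.finite(dy) & dy != 0
      numX[useX] <- numX[useX] + nx[useX]
      denX[useX] <- denX[useX] + dx[useX]
      numY[useY] <- numY[useY] + ny[useY]
      denY[useY] <- denY[useY] + dy[useY]
      nLoci <- nLoci + ok
    }
    rx <- ifelse(denX != 0, numX / denX, NA_real_)
    ry <- ifelse(denY != 0, numY / denY, NA_real_)
    value <- rowMeans(cbind(rx, ry), na.rm = TRUE)
    value[is.nan(value)] <- NA_real_
  } else {                                         # LOISELLE kinship
    num <- den <- numeric(nd)
    for (l in loci) {
      a <- xa1[, l]; b <- xa2[, l]; cc <- ya1[, l]; d <- ya2[, l]
      ok <- !is.na(a) & !is.na(cc)
      if (!any(ok)) next
      f <- freqs@freqs[[l]]
      sizes <- as.integer(names(f))
      n <- freqs@nGenes[l]
      corr <- if (is.finite(n) && n > 1) sum(f * (1 - f)) / (n - 1) else 0
      nl <- numeric(nd)
      for (s in seq_along(sizes)) {
        ps <- f[s]
        xs <- ((a == sizes[s]) + (b == sizes[s])) / 2
        ys <- ((cc == sizes[s]) + (d == sizes[s])) / 2
        nl <- nl + (xs - ps) * (ys - ps)
      }
      dl <- sum(f * (1 - f))
      if (dl == 0) next                            # monomorphic locus
      num[ok] <- num[ok] + nl[ok] + corr
      den[ok] <- den[ok] + dl
      nLoci <- nLoci + ok
    }
    value <- ifelse(den > 0, num / den, NA_real_)
  }
  list(value = value, nLoci = nLoci)
}

.dyadMatrices <- function(table, id1, id2) {
  i <- match(id1, table@meta$id); j <- match(id2, table@meta$id)
  if (anyNA(i) || anyNA(j)) stop("unknown individual id")
  list(xa1 = table@a1[i, , drop = FALSE], xa2 = table@a2[i, , drop = FALSE],
       ya1 = table@a1[j, , drop = FALSE], ya2 = table@a2[j, , drop = FALSE])
}

#' Pairwise relatedness between individuals
#'
#' Computes the Queller-Goodnight (QG) or Lynch-Ritland (LR) relatedness
#' coefficient, or the Loiselle kinship coefficient, for one or more dyads
#' against reference allele frequencies.  QG is the ratio-of-sums multilocus
#' form; LR uses the published locus weights; both are symmetrised as the
#' mean of the two reference orientations.  Loci missing in either member
#' are skipped, as are loci with a zero denominator for that orientation.
#'
#' @param table GenotypeTable
#' @param id1,id2 character vectors of equal length naming the dyads
#' @param freqs AlleleFreqTable
#' @param estimator "QG", "LR" or "LOISELLE"
#' @param minSharedLoci minimum shared typed loci for a defined estimate
#'   (default 5); with a single dyad below the minimum an error is raised,
#'   with several dyads the value is NA
#' @return data.frame with columns id1, id2, estimator, value, nLoci
#' @export
pairwiseRelatedness <- function(table, id1, id2, freqs,
                                estimator = c("QG", "LR", "LOISELLE"),
                                minSharedLoci = 5) {
  estimator <- match.arg(estimator)
  stopifnot(length(id1) == length(id2))
  m <- .dyadMatrices(table, id1, id2)
  r <- .relEngine(m$xa1, m$xa2, m$ya1, m$ya2, freqs, estimator)
  bad <- r$nLoci < minSharedLoci | is.na(r$value)
  if (length(id1) == 1 && bad)
    stop("estimate undefined: fewer than ", minSharedLoci,
         " usable shared loci for pair ", id1, "-", id2)
  r$value[bad] <- NA_real_
  data.frame(id1 = id1, id2 = id2, estimator = estimator,
             value = r$value, nLoci = r$nLoci, stringsAsFactors = FALSE)
}

#' All-pairs relatedness matrix
#'
#' Evaluates the chosen estimator over every unordered pair of a subset of
#' individuals.  Pairs sharing fewer than \code{minSharedLoci} typed loci
#' are present in the result but flagged undefined (NA value).
#'
#' @param table GenotypeTable
#' @param freqs AlleleFreqTable
#' @param estimator "QG", "LR" or "LOISELLE"
#' @param subset optional: character ids or a predicate over the metadata
#' @param minSharedLoci minimum shared typed loci (default 5)
#' @param pValues if TRUE, attach an allele-permutation p-value to every
#'   defined pair (see \code{\link{pairSignificanceTest}})
#' @param nPerm,seed permutation settings used when \code{pValues} is TRUE
#' @return \linkS4class{RelatednessMatrix}
#' @export
relatednessMatrix <- function(table, freqs,
                              estimator = c("QG", "LR", "LOISELLE"),
                              subset = NULL, minSharedLoci = 5,
                              pValues = FALSE, nPerm = 1000, seed = NULL) {
  estimator <- match.arg(estimator)
  ids <- table@meta$id
  if (is.function(subset)) ids <- ids[subset(table@meta)]
  else if (!is.null(subset)) ids <- intersect(ids, subset)
  if (length(ids) < 2) stop("need at least 2 individuals for a matrix")
  pr <- utils::combn(ids, 2)
  est <- pairwiseRelatedness(table, pr[1, ], pr[2, ], freqs, estimator,
                             minSharedLoci)
  est$p <- NA_real_
  if (pValues) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(nrow(est))) {
      if (is.na(est$value[k])) next
      est$p[k] <- pairSignificanceTest(table, est$id1[k], est$id2[k], freqs,
                                       estimator, nPerm = nPerm,
                                       seed = NULL)$p
    }
  }
  new("RelatednessMatrix", estimates = est, estimator = estimator,
      ids = ids, reference = freqs@referenceSet)
}

#' Allele-permutation significance of a pairwise relatedness value
#'
#' Builds the null distribution for "this pair is unrelated" by resampling,
#' at every locus typed in both members, each individual's two alleles from
#' the reference allele pool (frequency-weighted draws with replacement),
#' recomputing the estimator \code{nPerm} times.  The one-tailed p-value is
#' the fraction of null values greater than or equal to the observed value
#' (alternative: the pair is more related than random draws).
#'
#' @inheritParams pairwiseRelatedness
#' @param nPerm number of permutation replicates (warning below 100)
#' @param seed optional RNG seed
#' @param alternative "greater" (excess relatedness, default) or "two.sided"
#' @return one-row data.frame: id1, id2, estimator, value, nLoci, p
#' @export
pairSignificanceTest <- function(table, id1, id2, freqs,
                                 estimator = c("QG", "LR", "LOISELLE"),
                                 nPerm = 1000, seed = NULL,
                                 alternative = c("greater", "two.sided"),
                                 minSharedLoci = 5) {
  estimator <- match.arg(estimator)
  alternative <- match.arg(alternative)
  stopifnot(length(id1) == 1, length(id2) == 1)
  if (nPerm < 100) warning("nPerm < 100 gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  obs <- pairwiseRelatedness(table, id1, id2, freqs, estimator,
                             minSharedLoci)
  m <- .dyadMatrices(table, id1, id2)
  loci <- lociNames(freqs)
  mk <- function() matrix(NA_integer_, nPerm, length(loci),
                          dimnames = list(NULL, loci))
  xa1 <- mk(); xa2 <- mk(); ya1 <- mk(); ya2 <- mk()
  for (l in loci) {
    if (is.na(m$xa1[1, l]) || is.na(m$ya1[1, l])) next
    f <- freqs@freqs[[l]]
    g1 <- .drawAlleles(f, nPerm); g2 <- .drawAlleles(f, nPerm)
    h1 <- .drawAlleles(f, nPerm); h2 <- .drawAlleles(f, nPerm)
    xa1[, l] <- pmin(g1, g2); xa2[, l] <- pmax(g1, g2)
    ya1[, l] <- pmin(h1, h2); ya2[, l] <- pmax(h1, h2)
  }
  null <- .relEngine(xa1, xa2, ya1, ya2, freqs, estimator)$value
  null <- null[!is.na(null)]
  p <- mean(null >= obs$value)
  if (alternative == "two.sided")
    p <- min(1, 2 * min(p, mean(null <= obs$value)))
  out <- obs
  out$p <- p
  attr(out, "null") <- null
  out
}

#' Concordance between relatedness estimators
#'
#' Pearson correlation (and two-sided p) between every pair of relatedness
#' matrices over the dyads defined in both.
#'
#' @param matrices named list of \linkS4class{RelatednessMatrix} objects
#'   computed over the same individuals
#' @return data.frame: matrix1, matrix2, r, p, n
#' @export
estimatorConcordance <- function(matrices) {
  stopifnot(length(matrices) >= 2)
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m) m@estimator, "")
  key <- function(m) {
    e <- m@estimates
    paste(pmin(e$id1, e$id2), pmax(e$id1, e$id2))
  }
  k0 <- key(matrices[[1]])
  vals <- lapply(matrices, function(m) {
    kk <- key(m)
    if (!setequal(kk, k0)) stop("matrices must cover identical pair sets")
    m@estimates$value[match(k0, kk)]
  })
  cmb <- utils::combn(length(matrices), 2)
  out <- data.frame(matrix1 = names(matrices)[cmb[1, ]],
                    matrix2 = names(matrices)[cmb[2, ]],
                    r = NA_real_, p = NA_real_, n = NA_integer_)
  for (k in seq_len(ncol(cmb))) {
    x <- vals[[cmb[1, k]]]; y <- vals[[cmb[2, k]]]
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3) stop("fewer than 3 common defined pairs")
    if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0)
      stop("zero variance: correlation undefined")
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    out$r[k] <- unname(ct$estimate); out$p[k] <- ct$p.value
    out$n[k] <- sum(keep)
  }
  out
}

#' Export a RelatednessMatrix
#'
#' Long-format TSV (\code{id1,id2,estimator,value,n_loci,p}) or square CSV.
#'
#' @param x RelatednessMatrix
#' @param path output file
#' @param format "long" (TSV) or "square" (CSV)
#' @export
writeRelatednessMatrix <- function(x, path, format = c("long", "square")) {
  format <- match.arg(format)
  if (format == "long") {
    e <- x@estimates
    out <- data.frame(id1 = e$id1, id2 = e$id2, estimator = x@estimator,
                      value = e$value, n_loci = e$nLoci, p = e$p)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.csv(as.matrix(x), path)
  }
  invisible(path)
}
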