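# Likelihood parentage assignment with a per-genotype error model,
# simulation-calibrated delta confidence thresholds, mismatch counting and
# dyadic relationship likelihood ratios.
#
# Error model (Kalinowski class): with probability e the recorded genotype
# at a locus is an independent Hardy-Weinberg draw, otherwise the true
# genotype.  Marginally an errored genotype is still HWE, so mixtures stay
# closed-form.

#' Parentage analysis configuration
#'
#' @param errorRate per-genotype typing error rate (default 0.01)
#' @param propSampled assumed proportion of candidate parents sampled
#'   (default 0.5); used by the confidence simulation
#' @param confRelaxed,confStrict relaxed/strict confidence levels
#'   (defaults 0.80 and 0.95)
#' @param nSim simulated offspring for threshold calibration (default 10000)
#' @param lrThreshold significance threshold for relationship likelihood
#'   ratios (default 10)
#' @param minSharedLoci minimum shared typed loci for dyadic LRs (default 5)
#' @param seed optional RNG seed recorded in the config
#' @return list of class "ParentageConfig"
#' @export
parentageConfig <- function(errorRate = 0.01, propSampled = 0.5,
                            confRelaxed = 0.80, confStrict = 0.95,
                            nSim = 10000, lrThreshold = 10,
                            minSharedLoci = 5, seed = NULL) {
  stopifnot(errorRate >= 0, errorRate < 0.5,
            propSampled > 0, propSampled <= 1,
            confRelaxed < confStrict, confStrict < 1)
  structure(list(errorRate = errorRate, propSampled = propSampled,
                 confRelaxed = confRelaxed, confStrict = confStrict,
                 nSim = nSim, lrThreshold = lrThreshold,
                 minSharedLoci = minSharedLoci, seed = seed),
            class = "ParentageConfig")
}

# --- elementary locus probabilities, vectorised over loci or over dyads ---

# P(parent with genotype (q1,q2) transmits allele z)
.ptrans <- function(z, q1, q2) ((z == q1) + (z == q2)) / 2

# Hardy-Weinberg genotype probability of (o1,o2) with per-element freqs
.phwe <- function(po1, po2, hom) ifelse(hom, po1 * po2, 2 * po1 * po2)

# P(offspring (o1,o2) | single parent (q1,q2)), other parent from frequencies
.psingle <- function(o1, o2, q1, q2, po1, po2) {
  hom <- o1 == o2
  ifelse(hom, .ptrans(o1, q1, q2) * po1,
         .ptrans(o1, q1, q2) * po2 + .ptrans(o2, q1, q2) * po1)
}

# P(offspring | mother and father genotypes)
.ppair <- function(o1, o2, m1, m2, f1, f2) {
  hom <- o1 == o2
  ifelse(hom, .ptrans(o1, m1, m2) * .ptrans(o1, f1, f2),
         .ptrans(o1, m1, m2) * .ptrans(o2, f1, f2) +
           .ptrans(o2, m1, m2) * .ptrans(o1, f1, f2))
}

.freqLookup <- function(freqs, l, x) {
  f <- freqs@freqs[[l]]
  unname(f[match(x, as.integer(names(f)))])
}

# LOD vectorised over a block of dyads sharing the analysis type.
# off*/cand* are matrices (n x loci); mother may be NULL or matrices.
.lodEngine <- function(offA1, offA2, candA1, candA2, freqs, e,
                       mA1 = NULL, mA2 = NULL) {
  loci <- lociNames(freqs)
  n <- nrow(offA1)
  lod <- numeric(n); mism <- integer(n); used <- integer(n)
  neginf <- logical(n)
  for (l in loci) {
    o1 <- offA1[, l]; o2 <- offA2[, l]
    q1 <- candA1[, l]; q2 <- candA2[, l]
    ok <- !is.na(o1) & !is.na(q1)
    if (!is.null(mA1)) ok <- ok & !is.na(mA1[, l])
    if (!any(ok)) next
    po1 <- .freqLookup(freqs, l, o1); po2 <- .freqLookup(freqs, l, o2)
    hwe <- .phwe(po1, po2, o1 == o2)
    if (is.null(mA1)) {
      Tc <- .psingle(o1, o2, q1, q2, po1, po2)
      den <- hwe
      inc <- Tc == 0
    } else {
      m1 <- mA1[, l]; m2 <- mA2[, l]
      Tc <- .ppair(o1, o2, m1, m2, q1, q2)
      den <- .psingle(o1, o2, m1, m2, po1, po2)   # mother known, father random
      inc <- Tc == 0
      # a locus where even the mother-offspring duo is impossible is skipped
      # for the LOD (den = 0) but still counted as a candidate mismatch if
      # the trio fails while the duo does not
      zeroDen <- den == 0
      ok <- ok & !zeroDen
    }
    num <- (1 - e) * Tc + e * hwe
    denm <- (1 - e) * den + e * hwe
    contrib <- ifelse(num > 0, log(num) - log(denm), -Inf)
    neg <- ok & !is.finite(contrib)
    neginf <- neginf | neg
    lod[ok] <- lod[ok] + ifelse(is.finite(contrib[ok]), contrib[ok], 0)
    mism[ok] <- mism[ok] + inc[ok]
    used[ok] <- used[ok] + 1L
  }
  lod[neginf] <- -Inf
  list(lod = lod, mismatches = mism, nLoci = used)
}

.gmat <- function(table, ids) {
  i <- match(ids, table@meta$id)
  if (anyNA(i)) stop("unknown individual id: ",
                     paste(ids[is.na(i)], collapse = ", "))
  list(a1 = table@a1[i, , drop = FALSE], a2 = table@a2[i, , drop = FALSE])
}

#' LOD score of a candidate parent
#'
#' Natural-log likelihood ratio that the candidate is a parent of the
#' offspring versus an unrelated individual, summed over loci typed in all
#' involved genotypes, with the typing-error mixture applied to the
#' offspring genotype.  With a known other parent the comparison is
#' candidate-as-second-parent versus random-second-parent.  Mismatches count
#' loci that are Mendelian-incompatible ignoring error.  With
#' \code{errorRate = 0} an incompatible locus yields a \code{-Inf} LOD.
#'
#' @param table GenotypeTable
#' @param offspring,candidate individual ids (vectors of equal length allowed)
#' @param freqs AlleleFreqTable
#' @param knownOtherParent optional id (or vector) of the already-known
#'   parent for a second-parent analysis
#' @param config ParentageConfig
#' @return data.frame: offspring, candidate, lod, mismatches, nLoci
#' @export
parentageLod <- function(table, offspring, candidate, freqs,
                         knownOtherParent = NULL,
                         config = parentageConfig()) {
  n <- max(length(offspring), length(candidate))
  offspring <- rep_len(offspring, n); candidate <- rep_len(candidate, n)
  o <- .gmat(table, offspring); q <- .gmat(table, candidate)
  if (!is.null(knownOtherParent)) {
    m <- .gmat(table, rep_len(knownOtherParent, n))
    r <- .lodEngine(o$a1, o$a2, q$a1, q$a2, freqs, config$errorRate,
                    m$a1, m$a2)
  } else {
    r <- .lodEngine(o$a1, o$a2, q$a1, q$a2, freqs, config$errorRate)
  }
  if (any(r$nLoci == 0)) stop("offspring and candidate share no typed locus")
  data.frame(offspring = offspring, candidate = candidate, lod = r$lod,
             mismatches = r$mismatches, nLoci = r$nLoci,
             stringsAsFactors = FALSE)
}

# frequency-weighted allele draws, safe for single-allele loci
.drawAlleles <- function(f, n) {
  sizes <- as.integer(names(f))
  sizes[sample.int(length(sizes), n, replace = TRUE, prob = f)]
}

# simulate n HWE genotypes at the freqs panel; returns a1/a2 matrices
.simHweGenotypes <- function(freqs, n) {
  loci <- lociNames(freqs)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(NULL, loci))
  for (l in loci) {
    f <- freqs@freqs[[l]]
    g1 <- .drawAlleles(f, n)
    g2 <- .drawAlleles(f, n)
    a1[, l] <- pmin(g1, g2); a2[, l] <- pmax(g1, g2)
  }
  list(a1 = a1, a2 = a2)
}

# Mendelian offspring of parent pairs given as allele matrices
.simOffspringOf <- function(pa, pb) {
  n <- nrow(pa$a1)
  pick <- function(p) {
    u <- stats::runif(n * ncol(p$a1)) < 0.5
    m <- ifelse(u, p$a1, p$a2)
    matrix(m, n, dimnames = dimnames(p$a1))
  }
  g1 <- pick(pa); g2 <- pick(pb)
  list(a1 = pmin(g1, g2), a2 = pmax(g1, g2))
}

# replace each genotype with an HWE draw with probability e
.injectHweError <- function(g, freqs, e) {
  if (e <= 0) return(g)
  n <- nrow(g$a1)
  for (l in colnames(g$a1)) {
    hit <- which(stats::runif(n) < e & !is.na(g$a1[, l]))
    if (!length(hit)) next
    f <- freqs@freqs[[l]]
    x1 <- .drawAlleles(f, length(hit))
    x2 <- .drawAlleles(f, length(hit))
    g$a1[hit, l] <- pmin(x1, x2); g$a2[hit, l] <- pmax(x1, x2)
  }
  g
}

#' Simulate delta confidence thresholds
#'
#' Cervus-style calibration of the delta statistic (LOD of the best
#' candidate minus LOD of the second best).  \code{nSim} offspring are
#' simulated from the allele frequencies; for each, a candidate pool of
#' \code{nCandidates} parents contains the true parent with probability
#' \code{propSampled}, the rest being unrelated HWE individuals; the typing
#' error model is applied to every simulated genotype.  The threshold for a
#' confidence level is the smallest delta such that the proportion of
#' correct top candidates among assignments at or above it reaches the
#' level (+Inf with a warning when unreachable).
#'
#' @param freqs AlleleFreqTable
#' @param nCandidates candidate pool size per simulated offspring
#' @param config ParentageConfig (nSim, errorRate, propSampled, levels)
#' @param analysis "single" (one parent sought, other unknown) or "pair"
#'   (parent-pair analysis; pool size applies to each sex)
#' @param seed optional RNG seed (defaults to config$seed)
#' @return list of class "DeltaThresholds": strict, relaxed, analysis,
#'   successRate (proportion of simulations whose top candidate is correct),
#'   deltas/correct vectors for inspection
#' @export
simulateConfidenceThresholds <- function(freqs, nCandidates,
                                         config = parentageConfig(),
                                         analysis = c("single", "pair"),
                                         seed = config$seed) {
  analysis <- match.arg(analysis)
  stopifnot(nCandidates >= 1)
  if (!is.null(seed)) set.seed(seed)
  nSim <- config$nSim; e <- config$errorRate
  mother <- .simHweGenotypes(freqs, nSim)
  father <- .simHweGenotypes(freqs, nSim)
  off <- .simOffspringOf(mother, father)
  off <- .injectHweError(off, freqs, e)
  fatherObs <- .injectHweError(father, freqs, e)
  motherObs <- .injectHweError(mother, freqs, e)
  sampled <- stats::runif(nSim) < config$propSampled
  if (analysis == "single") {
    lods <- matrix(-Inf, nSim, nCandidates)
    for (k in seq_len(nCandidates)) {
      if (k == 1) {
        cand <- fatherObs            # slot 1 holds the true father when sampled
        unrel <- .simHweGenotypes(freqs, nSim)
        unrel <- .injectHweError(unrel, freqs, e)
        cand$a1[!sampled, ] <- unrel$a1[!sampled, ]
        cand$a2[!sampled, ] <- unrel$a2[!sampled, ]
      } else {
        cand <- .injectHweError(.simHweGenotypes(freqs, nSim), freqs, e)
      }
      lods[, k] <- .lodEngine(off$a1, off$a2, cand$a1, cand$a2, freqs, e)$lod
    }
    top <- max.col(lods, ties.method = "first")
    correct <- sampled & top == 1L
  } else {
    # parent-pair: true mother and father each sampled independently;
    # candidate pools of nCandidates per sex, exhaustive pair search
    sampledM <- stats::runif(nSim) < config$propSampled
    mPool <- list(); fPool <- list()
    for (k in seq_len(nCandidates)) {
      if (k == 1) {
        cm <- motherObs
        um <- .injectHweError(.simHweGenotypes(freqs, nSim), freqs, e)
        cm$a1[!sampledM, ] <- um$a1[!sampledM, ]
        cm$a2[!sampledM, ] <- um$a2[!sampledM, ]
        cf <- fatherObs
        uf <- .injectHweError(.simHweGenotypes(freqs, nSim), freqs, e)
        cf$a1[!sampled, ] <- uf$a1[!sampled, ]
        cf$a2[!sampled, ] <- uf$a2[!sampled, ]
      } else {
        cm <- .injectHweError(.simHweGenotypes(freqs, nSim), freqs, e)
        cf <- .injectHweError(.simHweGenotypes(freqs, nSim), freqs, e)
      }
      mPool[[k]] <- cm; fPool[[k]] <- cf
    }
    npair <- nCandidates^2
    lods <- matrix(-Inf, nSim, npair)
    col <- 0L
    for (i in seq_len(nCandidates)) for (j in seq_len(nCandidates)) {
      col <- col + 1L
      lods[, col] <- .trioLod(off, mPool[[i]], fPool[[j]], freqs, e)
    }
    top <- max.col(lods, ties.method = "first")
    correct <- sampledM & sampled & top == 1L   # pair (1,1) is the true pair
  }
  topLod <- lods[cbind(seq_len(nSim), top)]
  second <- if (ncol(lods) > 1)
    apply(lods, 1, function(z) sort(z, decreasing = TRUE)[2])
  else rep(-Inf, nSim)
  delta <- topLod - second
  delta[is.nan(delta) | is.na(delta)] <- 0   # -Inf vs -Inf: tie, no assignment
  delta[delta < 0] <- 0
  if (ncol(lods) > 1) correct <- correct & delta > 0   # exact ties: no assignment
  # smallest threshold t such that, among simulations with delta >= t
  # (tie-inclusive), the proportion of correct top candidates reaches the
  # level
  os <- order(delta, decreasing = TRUE)
  sortedDelta <- delta[os]
  cs <- cumsum(correct[os])
  lastIdx <- which(!duplicated(sortedDelta, fromLast = TRUE))
  fracs <- cs[lastIdx] / lastIdx
  pick <- function(level) {
    hit <- which(fracs >= level)
    if (!length(hit)) {
      warning(sprintf("confidence level %.2f unreachable; threshold +Inf",
                      level))
      return(Inf)
    }
    sortedDelta[lastIdx[max(hit)]]   # largest accepted set still at level
  }
  out <- list(strict = pick(config$confStrict),
              relaxed = pick(config$confRelaxed),
              analysis = analysis,
              successRate = mean(correct),
              deltas = delta, correct = correct)
  class(out) <- "DeltaThresholds"
  out
}

#' @export
print.DeltaThresholds <- function(x, ...) {
  cat(sprintf("Delta thresholds (%s analysis): strict %.3f, relaxed %.3f; top candidate correct in %.1f%% of simulations\n",
              x$analysis, x$strict, x$relaxed, 100 * x$successRate))
  invisible(x)
}

# trio LOD for genotype-matrix triples (internal, used by simulation)
.trioLod <- function(off, mother, father, freqs, e) {
  loci <- lociNames(freqs)
  n <- nrow(off$a1)
  lod <- numeric(n); neginf <- logical(n)
  for (l in loci) {
    o1 <- off$a1[, l]; o2 <- off$a2[, l]
    ok <- !is.na(o1) & !is.na(mother$a1[, l]) & !is.na(father$a1[, l])
    if (!any(ok)) next
    po1 <- .freqLookup(freqs, l, o1); po2 <- .freqLookup(freqs, l, o2)
    hwe <- .phwe(po1, po2, o1 == o2)
    Tc <- .ppair(o1, o2, mother$a1[, l], mother$a2[, l],
                 father$a1[, l], father$a2[, l])
    num <- (1 - e) * Tc + e * hwe
    contrib <- ifelse(num > 0, log(num) - log(hwe), -Inf)
    neg <- ok & !is.finite(contrib)
    neginf <- neginf | neg
    lod[ok] <- lod[ok] + ifelse(is.finite(contrib[ok]), contrib[ok], 0)
  }
  lod[neginf] <- -Inf
  lod
}

#' Assign parents to offspring
#'
#' For each offspring a joint parent-pair analysis is run first (exhaustive
#' search over mother x father candidates, trio LOD against the both-parents
#' -unrelated baseline); when no pair reaches relaxed confidence, separate
#' maternity and paternity single-parent analyses are run.  Confidence
#' classes come from simulated delta thresholds (computed here if not
#' supplied).  Exact LOD ties at the top leave the offspring unassigned.
#'
#' @param table GenotypeTable
#' @param offspring ids of individuals to assign
#' @param mothers,fathers candidate id sets (the offspring itself is
#'   excluded automatically)
#' @param freqs AlleleFreqTable
#' @param config ParentageConfig
#' @param thresholds optional list with elements \code{pair} and
#'   \code{single} (DeltaThresholds); simulated when NULL
#' @param seed optional RNG seed for the threshold simulation
#' @return data.frame of class "ParentageResult": one row per offspring and
#'   analysis with assigned candidates, lod, delta, mismatches, confidence
#' @export
assignParentage <- function(table, offspring, mothers, fathers, freqs,
                            config = parentageConfig(), thresholds = NULL,
                            seed = config$seed) {
  stopifnot(length(mothers) >= 1, length(fathers) >= 1)
  if (is.null(thresholds)) {
    thresholds <- list(
      pair = simulateConfidenceThresholds(freqs, max(length(mothers),
                                                     length(fathers)),
                                          config, "pair", seed = seed),
      single = simulateConfidenceThresholds(freqs, length(fathers),
                                            config, "single", seed = seed))
  }
  classify <- function(delta, thr) {
    if (is.na(delta) || is.nan(delta) || delta <= 0) return("none")
    if (delta >= thr$strict) "strict"
    else if (delta >= thr$relaxed) "relaxed" else "none"
  }
  rows <- list()
  for (o in offspring) {
    ms <- setdiff(mothers, o); fs <- setdiff(fathers, o)
    og <- .gmat(table, o)
    pairs <- expand.grid(mother = ms, father = fs,
                         stringsAsFactors = FALSE)
    mg <- .gmat(table, pairs$mother); fg <- .gmat(table, pairs$father)
    rep1 <- function(g, n) list(a1 = g$a1[rep(1, n), , drop = FALSE],
                                a2 = g$a2[rep(1, n), , drop = FALSE])
    lods <- .trioLod(rep1(og, nrow(pairs)), mg, fg, freqs, config$errorRate)
    ordd <- order(lods, decreasing = TRUE)
    best <- ordd[1]
    delta <- if (length(lods) > 1) lods[best] - lods[ordd[2]] else Inf
    tie <- length(lods) > 1 && lods[best] == lods[ordd[2]]
    conf <- if (tie) "none" else classify(delta, thresholds$pair)
    mm <- .trioMismatches(table, o, pairs$mother[best], pairs$father[best])
    rows[[length(rows) + 1L]] <- data.frame(
      offspring = o, analysis = "pair",
      mother = pairs$mother[best], father = pairs$father[best],
      lod = lods[best], delta = delta, mismatches = mm,
      confidence = if (tie) "none" else conf, stringsAsFactors = FALSE)
    if (conf == "none") {
      for (side in c("mother", "father")) {
        cand <- if (side == "mother") ms else fs
        sl <- parentageLod(table, rep(o, length(cand)), cand, freqs,
                           config = config)
        os <- order(sl$lod, decreasing = TRUE)
        b <- os[1]
        d <- if (length(cand) > 1) sl$lod[b] - sl$lod[os[2]] else Inf
        tie1 <- length(cand) > 1 && sl$lod[b] == sl$lod[os[2]]
        cf <- if (tie1) "none" else classify(d, thresholds$single)
        rows[[length(rows) + 1L]] <- data.frame(
          offspring = o, analysis = paste0("single_", side),
          mother = if (side == "mother") cand[b] else NA_character_,
          father = if (side == "father") cand[b] else NA_character_,
          lod = sl$lod[b], delta = d, mismatches = sl$mismatches[b],
          confidence = cf, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ParentageResult", class(out))
  out
}

# mismatch count of a trio against recorded genotypes, ignoring error
.trioMismatches <- function(table, off, mother, father) {
  o <- .gmat(table, off); m <- .gmat(table, mother); f <- .gmat(table, father)
  tl <- .ppair(o$a1[1, ], o$a2[1, ], m$a1[1, ], m$a2[1, ],
               f$a1[1, ], f$a2[1, ])
  ok <- !is.na(o$a1[1, ]) & !is.na(m$a1[1, ]) & !is.na(f$a1[1, ])
  sum(ok & tl == 0)
}

#' Dyadic relationship likelihood ratios
#'
#' For each unordered pair, the likelihood of the observed two genotypes is
#' computed under parent-offspring (PO), full-sib (FS), half-sib (HS) and
#' unrelated (U) IBD-coefficient models (k0,k1,k2) = (0,1,0), (1/4,1/2,1/4),
#' (1/2,1/2,0), (1,0,0), with the typing-error mixture folded in, and
#' reported as the multilocus likelihood ratio against U.  A relationship is
#' flagged significant when its LR exceeds \code{config$lrThreshold}
#' (default 10).  LR(U) is identically 1.
#'
#' @param table GenotypeTable
#' @param id1,id2 dyad id vectors (equal length)
#' @param freqs AlleleFreqTable
#' @param config ParentageConfig
#' @return data.frame: id1, id2, relationship, lr, significant
#' @export
relationshipLikelihoodRatios <- function(table, id1, id2, freqs,
                                         config = parentageConfig()) {
  stopifnot(length(id1) == length(id2))
  x <- .gmat(table, id1); y <- .gmat(table, id2)
  e <- config$errorRate
  loci <- lociNames(freqs)
  n <- length(id1)
  kcoef <- list(PO = c(0, 1, 0), FS = c(.25, .5, .25),
                HS = c(.5, .5, 0), U = c(1, 0, 0))
  logL <- matrix(0, n, length(kcoef), dimnames = list(NULL, names(kcoef)))
  shared <- integer(n)
  both <- (1 - e)^2
  for (l in loci) {
    x1 <- x$a1[, l]; x2 <- x$a2[, l]; y1 <- y$a1[, l]; y2 <- y$a2[, l]
    ok <- !is.na(x1) & !is.na(y1)
    if (!any(ok)) next
    px1 <- .freqLookup(freqs, l, x1); px2 <- .freqLookup(freqs, l, x2)
    py1 <- .freqLookup(freqs, l, y1); py2 <- .freqLookup(freqs, l, y2)
    Px <- .phwe(px1, px2, x1 == x2); Py <- .phwe(py1, py2, y1 == y2)
    P0 <- Px * Py
    P1 <- Px * .psingle(y1, y2, x1, x2, py1, py2)
    P2 <- Px * (x1 == y1 & x2 == y2)
    for (R in names(kcoef)) {
      k <- kcoef[[R]]
      PR <- k[1] * P0 + k[2] * P1 + k[3] * P2
      mix <- both * PR + (1 - both) * P0
      contrib <- ifelse(mix > 0, log(mix) - log(P0), -Inf)
      logL[ok, R] <- logL[ok, R] + contrib[ok]
    }
    shared <- shared + ok
  }
  if (any(shared < config$minSharedLoci))
    stop("some pairs share fewer than ", config$minSharedLoci,
         " typed loci")
  out <- expand.grid(row = seq_len(n), relationship = names(kcoef),
                     stringsAsFactors = FALSE)
  out <- data.frame(id1 = id1[out$row], id2 = id2[out$row],
                    relationship = out$relationship,
                    lr = exp(logL[cbind(out$row,
                                        match(out$relationship,
                                              colnames(logL)))]),
                    stringsAsFactors = FALSE)
  out$significant <- out$relationship != "U" & out$lr > config$lrThreshold
  out
}
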