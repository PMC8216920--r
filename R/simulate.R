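# Forward simulation with known truth: founder allele frequencies,
# fixed-relationship dyads, polygynous multi-group populations with female
# dispersal and extragroup paternity, stepwise mutation, genotyping-error
# injection, and behavioural proximity scans.

#' Simulation configuration
#'
#' Default values emulate the study system the package targets: a
#' ten-locus microsatellite panel with about seven alleles per locus and
#' expected heterozygosity near 0.75 in the final census (seven founder
#' alleles with Dirichlet(1.5) frequencies give founder E[He] = 0.78;
#' residual drift within the sampled group cluster brings the census close
#' to the 0.75 target), four
#' one-male breeding groups in two regions whose home-range centres are
#' 2-61 km apart, five adult females and one silverback per group plus four
#' solitary males, a small extragroup-paternity rate (2 of 27 offspring),
#' universal female natal dispersal biased towards the nearest neighbouring
#' group, wider-ranging male dispersal, and a 1 percent genotyping error
#' rate available for injection.
#'
#' @param nLoci number of microsatellite loci
#' @param allelesPerLocus founder alleles per locus
#' @param dirichletAlpha Dirichlet concentration for founder frequencies
#' @param alleleSizeRange inclusive integer bounds for allele sizes
#'   (repeat-scale units); mutation reflects at the edges
#' @param groups data.frame with columns group, country
#' @param distKm symmetric between-group distance matrix (km), dimnames =
#'   group names
#' @param femalesPerGroup breeding females per group
#' @param immaturesPerGroup offspring in the final census per group
#' @param nSolitary solitary adult males in the final census
#' @param extragroupPaternityRate probability an offspring is sired by a
#'   male other than its group's silverback
#' @param femaleDispersalRate probability a maturing female leaves her
#'   natal group (natal dispersal; default 1, universal)
#' @param nearestGroupProb dispersal-kernel mass on the nearest group; the
#'   remainder is split over farther groups proportionally to 1/distance
#' @param maleDispersalGlobal probability a breeding-male slot is filled
#'   from the population-wide male pool rather than natal-group sons
#' @param backgroundImmigrationRate probability that a recruited adult
#'   (female slot, breeding-male slot or solitary male) comes from the
#'   wider unsampled population (a Hardy-Weinberg draw at founder
#'   frequencies) instead of the study groups; the study groups are a
#'   small sample embedded in a continuous population, and this keeps the
#'   census near founder diversity instead of drifting as a closed deme
#'   set would.  Set to 0 for closed-population (pure drift) scenarios
#' @param generations forward generations before the final census
#' @param mutationRate stepwise (+/-1) mutation probability per transmitted
#'   allele
#' @param errorRate,dropoutRate,missingRate genotyping-artefact rates
#'   applied to the final census table
#' @return list of class "SimulationConfig"
#' @export
simulationConfig <- function(nLoci = 10, allelesPerLocus = 7,
                             dirichletAlpha = 1.5,
                             alleleSizeRange = c(8, 40),
                             groups = NULL, distKm = NULL,
                             femalesPerGroup = 5, immaturesPerGroup = 7,
                             nSolitary = 4,
                             extragroupPaternityRate = 2 / 27,
                             femaleDispersalRate = 1,
                             nearestGroupProb = 0.7,
                             maleDispersalGlobal = 0.8,
                             backgroundImmigrationRate = 0.25,
                             generations = 10, mutationRate = 5e-4,
                             errorRate = 0, dropoutRate = 0,
                             missingRate = 0) {
  if (is.null(groups))
    groups <- data.frame(group = c("CAR1", "CAR2", "RC1", "RC2"),
                         country = c("CAR", "CAR", "RC", "RC"),
                         stringsAsFactors = FALSE)
  if (is.null(distKm)) {
    g <- groups$group
    distKm <- matrix(0, length(g), length(g), dimnames = list(g, g))
    if (identical(g, c("CAR1", "CAR2", "RC1", "RC2"))) {
      d <- rbind(c(0, 9.1, 57, 58), c(9.1, 0, 61, 62),
                 c(57, 61, 0, 2), c(58, 62, 2, 0))
      dimnames(d) <- list(g, g)
      distKm <- d
    } else {
      # evenly spaced linear habitat, 10 km between neighbours
      pos <- 10 * (seq_along(g) - 1)
      distKm <- abs(outer(pos, pos, "-"))
      dimnames(distKm) <- list(g, g)
    }
  }
  rates <- c(extragroupPaternityRate, femaleDispersalRate,
             nearestGroupProb, maleDispersalGlobal,
             backgroundImmigrationRate, mutationRate,
             errorRate, dropoutRate, missingRate)
  stopifnot(all(rates >= 0 & rates <= 1), nrow(groups) >= 2,
            all(groups$group %in% rownames(distKm)),
            femalesPerGroup >= 1, generations >= 1)
  structure(list(nLoci = nLoci, allelesPerLocus = allelesPerLocus,
                 dirichletAlpha = dirichletAlpha,
                 alleleSizeRange = alleleSizeRange, groups = groups,
                 distKm = distKm[groups$group, groups$group],
                 femalesPerGroup = femalesPerGroup,
                 immaturesPerGroup = immaturesPerGroup,
                 nSolitary = nSolitary,
                 extragroupPaternityRate = extragroupPaternityRate,
                 femaleDispersalRate = femaleDispersalRate,
                 nearestGroupProb = nearestGroupProb,
                 maleDispersalGlobal = maleDispersalGlobal,
                 backgroundImmigrationRate = backgroundImmigrationRate,
                 generations = generations, mutationRate = mutationRate,
                 errorRate = errorRate, dropoutRate = dropoutRate,
                 missingRate = missingRate),
            class = "SimulationConfig")
}

#' Founder allele frequencies for a simulated panel
#'
#' Draws, for each locus, \code{allelesPerLocus} contiguous integer allele
#' sizes centred in the configured size range with Dirichlet-distributed
#' frequencies.  Returned as population (true) frequencies (nGenes = NA),
#' so downstream estimators apply no finite-sample correction.
#'
#' @param config SimulationConfig
#' @param seed optional RNG seed
#' @return \linkS4class{AlleleFreqTable}
#' @export
founderFrequencies <- function(config = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- config$allelesPerLocus
  lo <- config$alleleSizeRange[1]; hi <- config$alleleSizeRange[2]
  start <- lo + floor((hi - lo - k + 1) / 2)
  freqs <- vector("list", config$nLoci)
  names(freqs) <- sprintf("L%02d", seq_len(config$nLoci))
  for (l in seq_len(config$nLoci)) {
    g <- stats::rgamma(k, shape = config$dirichletAlpha)
    # guard against numerically degenerate draws
    g <- pmax(g, 1e-6)
    f <- g / sum(g)
    names(f) <- start:(start + k - 1)
    freqs[[l]] <- f
  }
  alleleFreqTable(freqs, nGenes = NA_real_,
                  referenceSet = "simulation founder truth")
}

# stepwise +/-1 mutation with reflecting bounds, applied in place
.smmMutate <- function(m, rate, range) {
  if (rate <= 0) return(m)
  n <- length(m)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(m)
  step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
  x <- m[hit] + step
  x[x < range[1]] <- range[1] + 1L
  x[x > range[2]] <- range[2] - 1L
  m[hit] <- x
  m
}

# Mendelian child of two parent genotype blocks (a1/a2 matrices) with SMM
.simChild <- function(mother, father, mi, fi, config) {
  L <- ncol(mother$a1)
  n <- length(mi)
  pickFrom <- function(p, idx) {
    u <- matrix(stats::runif(n * L) < 0.5, n, L)
    ifelse(u, p$a1[idx, , drop = FALSE], p$a2[idx, , drop = FALSE])
  }
  g1 <- .smmMutate(pickFrom(mother, mi), config$mutationRate,
                   config$alleleSizeRange)
  g2 <- .smmMutate(pickFrom(father, fi), config$mutationRate,
                   config$alleleSizeRange)
  dimnames(g1) <- dimnames(g2) <- list(NULL, colnames(mother$a1))
  list(a1 = pmin(g1, g2), a2 = pmax(g1, g2))
}

.bindGeno <- function(lst) {
  list(a1 = do.call(rbind, lapply(lst, `[[`, "a1")),
       a2 = do.call(rbind, lapply(lst, `[[`, "a2")))
}

#' Simulate dyads of fixed relationship
#'
#' Founders are drawn from Hardy-Weinberg at the founder frequencies and
#' offspring by Mendelian transmission (no mutation, no genotyping error),
#' producing exactly \code{nDyads} dyads of the requested relationship:
#' parent-offspring (PO), full siblings (FS), paternal half siblings (HS)
#' or unrelated (U).
#'
#' @param config SimulationConfig
#' @param relationship "PO", "FS", "HS" or "U"
#' @param nDyads number of dyads
#' @param seed optional RNG seed
#' @param freqs optional AlleleFreqTable (generated from config when NULL)
#' @return list: table (GenotypeTable; dyad i is ids "Di_x"/"Di_y"),
#'   dyads (data.frame id1, id2, relationship), freqs
#' @export
simulateRelationshipDyads <- function(config = simulationConfig(),
                                      relationship = c("PO", "FS", "HS", "U"),
                                      nDyads, seed = NULL, freqs = NULL) {
  relationship <- match.arg(relationship)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) freqs <- founderFrequencies(config)
  n <- nDyads
  noMut <- config; noMut$mutationRate <- 0
  idx <- seq_len(n)
  x <- y <- NULL
  if (relationship == "U") {
    x <- .simHweGenotypes(freqs, n); y <- .simHweGenotypes(freqs, n)
  } else if (relationship == "PO") {
    x <- .simHweGenotypes(freqs, n)
    mate <- .simHweGenotypes(freqs, n)
    y <- .simChild(x, mate, idx, idx, noMut)
  } else if (relationship == "FS") {
    m <- .simHweGenotypes(freqs, n); f <- .simHweGenotypes(freqs, n)
    x <- .simChild(m, f, idx, idx, noMut)
    y <- .simChild(m, f, idx, idx, noMut)
  } else {                                     # HS: shared father
    f <- .simHweGenotypes(freqs, n)
    m1 <- .simHweGenotypes(freqs, n); m2 <- .simHweGenotypes(freqs, n)
    x <- .simChild(m1, f, idx, idx, noMut)
    y <- .simChild(m2, f, idx, idx, noMut)
  }
  ids <- c(sprintf("D%d_x", idx), sprintf("D%d_y", idx))
  a1 <- rbind(x$a1, y$a1); a2 <- rbind(x$a2, y$a2)
  rownames(a1) <- rownames(a2) <- ids
  tab <- GenotypeTable(a1, a2, data.frame(id = ids))
  list(table = tab,
       dyads = data.frame(id1 = sprintf("D%d_x", idx),
                          id2 = sprintf("D%d_y", idx),
                          relationship = relationship,
                          stringsAsFactors = FALSE),
       freqs = freqs)
}

#' Inject genotyping artefacts into a table
#'
#' Per genotype (individual x locus), independently: with
#' \code{missingRate} the genotype is set missing; with \code{dropoutRate}
#' a heterozygote loses one allele (becomes the homozygote of the other);
#' with \code{errorRate} the genotype is replaced by a random
#' Hardy-Weinberg draw from \code{freqs}.
#'
#' @param table GenotypeTable
#' @param errorRate,dropoutRate,missingRate rates in [0,1]
#' @param freqs AlleleFreqTable used for error draws (estimated from the
#'   table itself when NULL)
#' @param seed optional RNG seed
#' @return GenotypeTable with artefacts applied
#' @export
injectGenotypingError <- function(table, errorRate = 0.01,
                                  dropoutRate = 0, missingRate = 0,
                                  freqs = NULL, seed = NULL) {
  stopifnot(errorRate >= 0, errorRate <= 1, dropoutRate >= 0,
            dropoutRate <= 1, missingRate >= 0, missingRate <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (errorRate > 0 && is.null(freqs)) freqs <- alleleFrequencies(table)
  a1 <- table@a1; a2 <- table@a2
  n <- nrow(a1)
  for (l in colnames(a1)) {
    typed <- !is.na(a1[, l])
    if (errorRate > 0) {
      hit <- which(typed & stats::runif(n) < errorRate)
      if (length(hit)) {
        f <- freqs@freqs[[l]]
        x1 <- .drawAlleles(f, length(hit))
        x2 <- .drawAlleles(f, length(hit))
        a1[hit, l] <- pmin(x1, x2); a2[hit, l] <- pmax(x1, x2)
      }
    }
    if (dropoutRate > 0) {
      het <- typed & a1[, l] != a2[, l]
      hit <- which(het & stats::runif(n) < dropoutRate)
      if (length(hit)) {
        keepFirst <- stats::runif(length(hit)) < 0.5
        kept <- ifelse(keepFirst, a1[hit, l], a2[hit, l])
        a1[hit, l] <- kept; a2[hit, l] <- kept
      }
    }
    if (missingRate > 0) {
      hit <- which(typed & stats::runif(n) < missingRate)
      a1[hit, l] <- NA_integer_; a2[hit, l] <- NA_integer_
    }
  }
  GenotypeTable(a1, a2, table@meta)
}

# size-safe sampling from an index vector (never the 1:n surprise)
.sampleVec <- function(x, k, replace = FALSE) {
  if (k > length(x) && !replace) replace <- TRUE
  x[sample.int(length(x), k, replace = replace)]
}

# female dispersal kernel over groups: nearest neighbour gets mass q, the
# rest is split over farther groups proportionally to inverse distance
.dispersalKernel <- function(config, from) {
  g <- config$groups$group
  d <- config$distKm[from, g]
  others <- g[g != from]
  do <- d[others]
  pr <- stats::setNames(numeric(length(others)), others)
  nearest <- others[which.min(do)]
  if (length(others) == 1) { pr[nearest] <- 1; return(pr) }
  pr[nearest] <- config$nearestGroupProb
  rest <- setdiff(others, nearest)
  w <- 1 / do[rest]
  pr[rest] <- (1 - config$nearestGroupProb) * w / sum(w)
  pr
}

#' Forward-simulate a multi-group polygynous population
#'
#' Non-overlapping generations with a fixed census per group: each group
#' holds one breeding silverback and a fixed number of adult females.  Each
#' generation every group produces offspring (mothers drawn from group
#' females; the sire is the group silverback except with the configured
#' extragroup-paternity probability, in which case an outside male —
#' another group's silverback or a solitary male — is drawn at random);
#' transmitted alleles mutate by single steps at the configured rate.
#' Maturing females disperse under the distance-biased kernel; breeding
#' male slots are filled from the population-wide or natal son pool; a
#' fixed number of surplus males remain as solitary males.  After the final
#' generation a census of immature offspring is produced per group (with
#' recorded mothers and fathers), and configured genotyping artefacts are
#' applied to the output table.
#'
#' @param config SimulationConfig
#' @param seed optional RNG seed
#' @return list: table (GenotypeTable of the final census), truth (list
#'   with pedigree data.frame of the census immatures: id, mother, father,
#'   group, extragroup flag; femaleOrigin data.frame: id, natalGroup,
#'   group), locations (data.frame group, country), distKm, freqs (founder
#'   AlleleFreqTable)
#' @export
simulatePopulation <- function(config = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- founderFrequencies(config)
  g <- config$groups$group
  nf <- config$femalesPerGroup
  fem <- lapply(g, function(gg) .simHweGenotypes(freqs, nf))
  names(fem) <- g
  femNatal <- lapply(g, function(gg) rep(gg, nf)); names(femNatal) <- g
  sb <- lapply(g, function(gg) .simHweGenotypes(freqs, 1)); names(sb) <- g
  sol <- .simHweGenotypes(freqs, max(config$nSolitary, 1))
  kernels <- lapply(g, function(gg) .dispersalKernel(config, gg))
  names(kernels) <- g
  outsideMales <- function(gg) {
    ms <- .bindGeno(c(sb[setdiff(g, gg)], list(sol)))
    ms
  }
  for (t in seq_len(config$generations)) {
    nOff <- 4 * nf
    kidList <- list(); kidSex <- character(); kidNatal <- character()
    for (gg in g) {
      mi <- sample.int(nf, nOff, replace = TRUE)
      egp <- stats::runif(nOff) < config$extragroupPaternityRate
      own <- .simChild(fem[[gg]], sb[[gg]], mi, rep(1L, nOff), config)
      kids <- own
      if (any(egp)) {
        om <- outsideMales(gg)
        fi <- sample.int(nrow(om$a1), sum(egp), replace = TRUE)
        ek <- .simChild(fem[[gg]], om, mi[egp], fi, config)
        kids$a1[egp, ] <- ek$a1; kids$a2[egp, ] <- ek$a2
      }
      kidList[[gg]] <- kids
      kidSex <- c(kidSex, sample(c("female", "male"), nOff,
                                 replace = TRUE))
      kidNatal <- c(kidNatal, rep(gg, nOff))
    }
    kids <- .bindGeno(kidList)
    isF <- kidSex == "female"
    # daughters disperse, then each group recruits its next female cohort
    dNatal <- kidNatal[isF]
    dTarget <- vapply(dNatal, function(nat) {
      if (stats::runif(1) >= config$femaleDispersalRate) return(nat)
      kr <- kernels[[nat]]
      sample(names(kr), 1, prob = kr)
    }, "")
    dIdx <- which(isF)
    for (gg in g) {
      here <- dIdx[dTarget == gg]
      if (length(here) < nf)  # top up from the whole daughter pool
        here <- c(here, .sampleVec(setdiff(dIdx, here),
                                   nf - length(here)))
      pick <- if (length(here) > nf) .sampleVec(here, nf) else here
      newFem <- list(a1 = kids$a1[pick, , drop = FALSE],
                     a2 = kids$a2[pick, , drop = FALSE])
      natal <- kidNatal[pick]
      bg <- which(stats::runif(nf) < config$backgroundImmigrationRate)
      if (length(bg)) {
        imm <- .simHweGenotypes(freqs, length(bg))
        newFem$a1[bg, ] <- imm$a1; newFem$a2[bg, ] <- imm$a2
        natal[bg] <- "outside"
      }
      fem[[gg]] <- newFem
      femNatal[[gg]] <- natal
    }
    sons <- which(!isF)
    if (length(sons) < length(g) + config$nSolitary)
      sons <- seq_along(kidSex)                 # degenerate safeguard
    taken <- integer()
    for (gg in g) {
      pool <- if (stats::runif(1) < config$maleDispersalGlobal)
        setdiff(sons, taken)
      else {
        own <- setdiff(sons[kidNatal[sons] == gg], taken)
        if (length(own)) own else setdiff(sons, taken)
      }
      pick <- .sampleVec(pool, 1)
      if (stats::runif(1) < config$backgroundImmigrationRate)
        sb[[gg]] <- .simHweGenotypes(freqs, 1)
      else
        sb[[gg]] <- list(a1 = kids$a1[pick, , drop = FALSE],
                         a2 = kids$a2[pick, , drop = FALSE])
      taken <- c(taken, pick)
    }
    rem <- setdiff(sons, taken)
    solPick <- .sampleVec(rem, min(config$nSolitary, max(length(rem), 1)))
    sol <- list(a1 = kids$a1[solPick, , drop = FALSE],
                a2 = kids$a2[solPick, , drop = FALSE])
    nbg <- sum(stats::runif(nrow(sol$a1)) < config$backgroundImmigrationRate)
    if (nbg) {
      imm <- .simHweGenotypes(freqs, nbg)
      sol$a1[seq_len(nbg), ] <- imm$a1; sol$a2[seq_len(nbg), ] <- imm$a2
    }
  }
  # final census: adults plus immatures with recorded parentage
  ids <- character(); rows1 <- list(); rows2 <- list()
  meta <- list()
  ped <- list()
  femaleOrigin <- list()
  countryOf <- stats::setNames(config$groups$country, g)
  addInd <- function(geno, i, id, sex, age, role, grp) {
    ids <<- c(ids, id)
    rows1[[length(rows1) + 1L]] <<- geno$a1[i, , drop = FALSE]
    rows2[[length(rows2) + 1L]] <<- geno$a2[i, , drop = FALSE]
    meta[[length(meta) + 1L]] <<- data.frame(
      id = id, sex = sex, age_class = age, role = role, group = grp,
      country = unname(countryOf[grp]), stringsAsFactors = FALSE)
  }
  for (gg in g) {
    addInd(sb[[gg]], 1, paste0(gg, "_SB"), "male", "adult",
           "silverback", gg)
    for (i in seq_len(nf)) {
      fid <- sprintf("%s_AF%d", gg, i)
      addInd(fem[[gg]], i, fid, "female", "adult", "adult_female", gg)
      femaleOrigin[[length(femaleOrigin) + 1L]] <-
        data.frame(id = fid, natalGroup = femNatal[[gg]][i], group = gg,
                   stringsAsFactors = FALSE)
    }
  }
  solHost <- sample(g, nrow(sol$a1), replace = TRUE)
  for (i in seq_len(nrow(sol$a1)))
    addInd(sol, i, sprintf("SOL%d", i), "male", "adult",
           "solitary_male", solHost[i])
  for (gg in g) {
    nIm <- config$immaturesPerGroup
    if (nIm < 1) next
    mi <- sample.int(nf, nIm, replace = TRUE)
    egp <- stats::runif(nIm) < config$extragroupPaternityRate
    om <- outsideMales(gg)
    omIds <- c(paste0(setdiff(g, gg), "_SB"),
               sprintf("SOL%d", seq_len(nrow(sol$a1))))
    fi <- sample.int(nrow(om$a1), nIm, replace = TRUE)
    kid <- .simChild(fem[[gg]], sb[[gg]], mi, rep(1L, nIm), config)
    if (any(egp)) {
      ek <- .simChild(fem[[gg]], om, mi[egp], fi[egp], config)
      kid$a1[egp, ] <- ek$a1; kid$a2[egp, ] <- ek$a2
    }
    for (i in seq_len(nIm)) {
      iid <- sprintf("%s_IM%d", gg, i)
      addInd(kid, i, iid, sample(c("female", "male"), 1), "immature",
             "immature", gg)
      ped[[length(ped) + 1L]] <- data.frame(
        id = iid, mother = sprintf("%s_AF%d", gg, mi[i]),
        father = if (egp[i]) omIds[fi[i]] else paste0(gg, "_SB"),
        group = gg, extragroup = egp[i], stringsAsFactors = FALSE)
    }
  }
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  rownames(a1) <- rownames(a2) <- ids
  tab <- GenotypeTable(a1, a2, do.call(rbind, meta))
  if (config$errorRate > 0 || config$dropoutRate > 0 ||
      config$missingRate > 0)
    tab <- injectGenotypingError(tab, config$errorRate,
                                 config$dropoutRate, config$missingRate,
                                 freqs = freqs)
  list(table = tab,
       truth = list(pedigree = do.call(rbind, ped),
                    femaleOrigin = do.call(rbind, femaleOrigin)),
       locations = data.frame(group = g,
                              country = config$groups$country,
                              stringsAsFactors = FALSE),
       distKm = config$distKm, freqs = freqs)
}

#' Simulate behavioural proximity scans for dyads
#'
#' Draws, for each dyad, a fixed number of instantaneous scans: with the
#' dyad's near probability the scan falls within 10 m (split evenly between
#' the 0-5 m and 6-10 m categories), otherwise it is >= 10 m.
#'
#' @param dyads data.frame with columns id1, id2
#' @param scansPerDyad scans per dyad
#' @param hoursPerDyad focal hours per dyad (recycled)
#' @param nearProb per-dyad probability of a < 10 m scan (recycled)
#' @param seed optional RNG seed
#' @return list: scans (focal, partner, category), hours (id1, id2, hours)
#' @export
simulateProximityScans <- function(dyads, scansPerDyad, hoursPerDyad,
                                   nearProb, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nd <- nrow(dyads)
  nearProb <- rep_len(nearProb, nd)
  hoursPerDyad <- rep_len(hoursPerDyad, nd)
  stopifnot(all(nearProb >= 0 & nearProb <= 1))
  if (scansPerDyad < 1)
    return(list(scans = data.frame(focal = character(),
                                   partner = character(),
                                   category = character()),
                hours = data.frame(id1 = dyads$id1, id2 = dyads$id2,
                                   hours = hoursPerDyad)))
  scans <- do.call(rbind, lapply(seq_len(nd), function(k) {
    near <- stats::runif(scansPerDyad) < nearProb[k]
    cat <- ifelse(near,
                  sample(c("0-5m", "6-10m"), scansPerDyad, replace = TRUE),
                  ">=10m")
    data.frame(focal = dyads$id1[k], partner = dyads$id2[k],
               category = cat, stringsAsFactors = FALSE)
  }))
  list(scans = scans,
       hours = data.frame(id1 = dyads$id1, id2 = dyads$id2,
                          hours = hoursPerDyad, stringsAsFactors = FALSE))
}
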