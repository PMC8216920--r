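# Spatial genetic structure: geographic distances, allele-size based R_ST
# with permutation significance, isolation-by-distance regression with a
# location-permutation (Mantel-type) test.

#' Pairwise geographic distance matrix between groups
#'
#' Geodesic (haversine, WGS84 mean radius 6371.0088 km) distances in km
#' between group home-range centre points.  A supplied override matrix wins
#' over coordinates and is the canonical path when published between-site
#' distances are to be used directly.
#'
#' @param locations data.frame with columns group, lat, lon (decimal
#'   degrees, WGS84) and optionally country; lat/lon may be NA when an
#'   override is supplied
#' @param override optional square matrix of distances (km) with group
#'   dimnames; validated and returned as-is
#' @return symmetric matrix of distances in km, zero diagonal
#' @export
geographicDistanceMatrix <- function(locations, override = NULL) {
  groups <- as.character(locations$group)
  if (!is.null(override)) {
    override <- as.matrix(override)
    if (is.null(dimnames(override)) ||
        !all(groups %in% rownames(override)))
      stop("override matrix must have group dimnames covering all groups")
    m <- override[groups, groups]
    if (any(abs(m - t(m)) > 1e-9) || any(diag(m) != 0))
      stop("override matrix must be symmetric with a zero diagonal")
    return(m)
  }
  if (any(is.na(locations$lat) | is.na(locations$lon)))
    stop("missing coordinates for group(s): ",
         paste(groups[is.na(locations$lat) | is.na(locations$lon)],
               collapse = ", "))
  if (any(abs(locations$lat) > 90) || any(abs(locations$lon) > 180))
    stop("coordinates out of range")
  xy <- cbind(locations$lon, locations$lat)
  m <- geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371008.8)) / 1000
  dimnames(m) <- list(groups, groups)
  m
}

# per-locus one-way ANOVA on allele sizes (gene copies as observations);
# returns among- and within-population variance components
.rstComponents <- function(sizes, pop) {
  k <- length(unique(pop))
  N <- length(sizes)
  if (k < 2 || N <= k) return(c(sb = 0, sw = 0))
  gm <- mean(sizes)
  pm <- tapply(sizes, pop, mean)
  ni <- tapply(sizes, pop, length)
  ssb <- sum(ni * (pm[names(ni)] - gm)^2)
  ssw <- sum((sizes - pm[pop])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  # negative among-population components are truncated at zero, so that
  # populations with identical allele-size compositions give R_ST = 0
  c(sb = max((msb - msw) / n0, 0), sw = msw)
}

.rstValue <- function(a1, a2, popOfInd) {
  sb <- sw <- 0
  for (l in seq_len(ncol(a1))) {
    g1 <- a1[, l]; g2 <- a2[, l]
    ok <- !is.na(g1)
    if (sum(ok) < 2) next
    sizes <- c(g1[ok], g2[ok])
    pop <- c(popOfInd[ok], popOfInd[ok])
    v <- .rstComponents(sizes, pop)
    sb <- sb + v["sb"]; sw <- sw + v["sw"]
  }
  tot <- sb + sw
  if (tot <= 0) return(NA_real_)
  unname(sb / tot)
}

#' Allele-size based population differentiation (R_ST)
#'
#' Variance-components estimator of R_ST: at each locus, a one-way ANOVA of
#' allele sizes over populations (gene copies as observations) yields
#' among-population and within-population components; the multilocus R_ST
#' is the summed among component over the summed total, the differentiation
#' index appropriate for microsatellites evolving under stepwise mutation.
#' Significance of the global value is assessed by permuting individuals
#' among populations; pairwise values are returned for every population
#' pair.
#'
#' @param table GenotypeTable
#' @param partition named vector id -> population label
#' @param nPerm permutations for the global test (default 10000)
#' @param seed optional RNG seed
#' @return list of class "RstResult": global (rst, p, nPerm, seed),
#'   pairwise data.frame (pop1, pop2, rst), partition description
#' @export
rstStatistic <- function(table, partition, nPerm = 10000, seed = NULL) {
  ids <- names(partition)
  if (is.null(ids)) stop("partition must be a named vector (names = ids)")
  i <- match(ids, table@meta$id)
  if (anyNA(i)) stop("unknown individual id in partition")
  a1 <- table@a1[i, , drop = FALSE]; a2 <- table@a2[i, , drop = FALSE]
  pop <- as.character(partition)
  pops <- unique(pop)
  if (length(pops) < 2) stop("need at least two populations")
  obs <- .rstValue(a1, a2, pop)
  if (is.na(obs))
    stop("allele-size variance is zero: R_ST undefined for this panel")
  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(nPerm)
  for (b in seq_len(nPerm)) perm[b] <- .rstValue(a1, a2, sample(pop))
  p <- sum(perm >= obs, na.rm = TRUE) / nPerm
  pw <- utils::combn(pops, 2)
  pairwise <- data.frame(pop1 = pw[1, ], pop2 = pw[2, ], rst = NA_real_,
                         stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pw))) {
    sel <- pop %in% pw[, k]
    pairwise$rst[k] <- .rstValue(a1[sel, , drop = FALSE],
                                 a2[sel, , drop = FALSE], pop[sel])
  }
  structure(list(global = list(rst = obs, p = p, nPerm = nPerm,
                               seed = seed, null = perm),
                 pairwise = pairwise,
                 partition = paste(pops, collapse = " vs ")),
            class = "RstResult")
}

#' @export
print.RstResult <- function(x, ...) {
  cat(sprintf("Global R_ST (%s) = %.4f, p = %.4g (%d permutations)\n",
              x$partition, x$global$rst, x$global$p, x$global$nPerm))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Isolation-by-distance regression with location-permutation test
#'
#' Ordinary least squares of R_ST/(1-R_ST) on the natural logarithm of
#' pairwise geographic distance (km), the linearisation expected to have a
#' positive slope under a two-dimensional isolation-by-distance model.
#' Significance: the location assignment of populations is permuted
#' \code{nPerm} times (the R_ST table stays fixed, distances are recomputed
#' under each assignment — equivalent to a Mantel test) and the one-tailed
#' p is the fraction of permuted slopes at or above the observed slope.
#' Pairs with R_ST = 1 (infinite transform) are excluded with a warning.
#'
#' @param pairwiseRst data.frame with columns pop1, pop2, rst (as produced
#'   by \code{\link{rstStatistic}})
#' @param distances symmetric distance matrix (km) with population dimnames
#' @param nPerm permutations (default 10000)
#' @param seed optional RNG seed
#' @return list of class "IbdResult": slope, intercept, p, nPerm, seed,
#'   table (pop pair, distanceKm, rst, rstRatio), logBase = "natural"
#' @export
ibdRegression <- function(pairwiseRst, distances, nPerm = 10000,
                          seed = NULL) {
  pops <- unique(c(pairwiseRst$pop1, pairwiseRst$pop2))
  if (length(pops) < 3) stop("need at least three populations")
  if (!all(pops %in% rownames(distances)))
    stop("distance matrix lacks some populations")
  d <- distances[cbind(pairwiseRst$pop1, pairwiseRst$pop2)]
  if (any(d <= 0)) stop("all pairwise distances must be > 0")
  ratio <- pairwiseRst$rst / (1 - pairwiseRst$rst)
  keep <- is.finite(ratio)
  if (!all(keep))
    warning("excluding ", sum(!keep), " pair(s) with R_ST = 1")
  if (sum(keep) < 3) stop("fewer than 3 usable pairs")
  tab <- data.frame(pop1 = pairwiseRst$pop1[keep],
                    pop2 = pairwiseRst$pop2[keep],
                    distanceKm = d[keep], rst = pairwiseRst$rst[keep],
                    rstRatio = ratio[keep])
  x <- log(tab$distanceKm); y <- tab$rstRatio
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  if (!is.null(seed)) set.seed(seed)
  permSlopes <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    relab <- sample(pops)
    names(relab) <- pops
    xd <- log(distances[cbind(relab[tab$pop1], relab[tab$pop2])])
    permSlopes[b] <- stats::cov(xd, y) / stats::var(xd)
  }
  p <- sum(permSlopes >= slope) / nPerm
  structure(list(slope = slope, intercept = intercept, p = p,
                 nPerm = nPerm, seed = seed, table = tab,
                 null = permSlopes, logBase = "natural"),
            class = "IbdResult")
}

#' @export
print.IbdResult <- function(x, ...) {
  cat(sprintf("Isolation by distance: slope = %.4f (log-%s distance), intercept = %.4f, one-tailed p = %.4g (%d location permutations)\n",
              x$slope, x$logBase, x$intercept, x$p, x$nPerm))
  invisible(x)
}

#' Export an IBD result as TSV (pair table) and JSON (fit summary)
#' @param x IbdResult
#' @param tsvPath,jsonPath output paths (either may be NULL)
#' @export
writeIbdResult <- function(x, tsvPath = NULL, jsonPath = NULL) {
  if (!is.null(tsvPath))
    utils::write.table(x$table, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(list(slope = x$slope, intercept = x$intercept,
                              p = x$p, nPerm = x$nPerm,
                              logBase = x$logBase),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(x)
}
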