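# Behavioural proximity: dyadic scan counts into scans-per-hour indices,
# and their rank correlation with genetic relatedness.

.proxCategories <- c("0-5m", "6-10m", ">=10m", "unrecorded")

#' Build dyadic proximity indices from scan records
#'
#' Instantaneous scan records (focal, partner, category) are pooled over
#' both focal directions of each unordered dyad.  "Near" scans are the
#' 0-5 m and 6-10 m categories; a scan whose distance was not recorded is
#' treated as >= 10 m.  The index is near scans per focal hour for the
#' dyad.
#'
#' @param scans data.frame with columns focal, partner, category (one of
#'   \code{"0-5m"}, \code{"6-10m"}, \code{">=10m"}, \code{"unrecorded"});
#'   a timestamp column may be present and is ignored by the arithmetic
#' @param hours data.frame with columns id1, id2, hours: focal observation
#'   hours per unordered dyad
#' @return data.frame of class "DyadProximity": id1, id2, nScansNear,
#'   nScansTotal, hours, index
#' @export
buildDyadProximity <- function(scans, hours) {
  stopifnot(all(c("focal", "partner", "category") %in% names(scans)),
            all(c("id1", "id2", "hours") %in% names(hours)))
  if (nrow(scans) && any(scans$focal == scans$partner))
    stop("scan with focal == partner")
  bad <- !scans$category %in% .proxCategories
  if (any(bad))
    stop("unknown scan category: ",
         paste(unique(scans$category[bad]), collapse = ", "))
  dk <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  hkey <- dk(hours$id1, hours$id2)
  if (anyDuplicated(hkey)) stop("duplicate dyad in hours table")
  if (any(!is.finite(hours$hours) | hours$hours <= 0))
    stop("hours must be positive for every dyad")
  skey <- if (nrow(scans)) dk(scans$focal, scans$partner) else character()
  missing <- setdiff(unique(skey), hkey)
  if (length(missing))
    stop("no observation hours for observed dyad(s): ",
         paste(missing, collapse = ", "))
  near <- scans$category %in% c("0-5m", "6-10m")
  nNear <- tapply(near, skey, sum)
  nTot <- tapply(near, skey, length)
  out <- data.frame(
    id1 = sub("\\|.*", "", hkey), id2 = sub(".*\\|", "", hkey),
    nScansNear = as.integer(ifelse(is.na(nNear[hkey]), 0L, nNear[hkey])),
    nScansTotal = as.integer(ifelse(is.na(nTot[hkey]), 0L, nTot[hkey])),
    hours = hours$hours, stringsAsFactors = FALSE)
  out$index <- out$nScansNear / out$hours
  class(out) <- c("DyadProximity", class(out))
  out
}

#' Spearman correlation between proximity and relatedness
#'
#' Rank correlation (average-rank tie handling) between the dyadic
#' proximity index and the pairwise relatedness estimate, over dyads with
#' both measures defined.  An exact p-value is used for n <= 10 when there
#' are no ties, the large-sample approximation otherwise.
#'
#' @param proximity DyadProximity data.frame
#' @param rmat RelatednessMatrix
#' @return list: rho, p (two-sided), n
#' @export
proximityRelatednessCorrelation <- function(proximity, rmat) {
  M <- as.matrix(rmat)
  keep <- proximity$id1 %in% rownames(M) & proximity$id2 %in% rownames(M)
  x <- proximity$index[keep]
  r <- M[cbind(proximity$id1[keep], proximity$id2[keep])]
  ok <- !is.na(r)
  x <- x[ok]; r <- r[ok]
  if (length(x) < 3) stop("need at least 3 dyads with both measures")
  if (stats::sd(x) == 0 || stats::sd(r) == 0)
    stop("constant vector: correlation undefined")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(r) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, r, method = "spearman",
                    exact = length(x) <= 10 && !ties))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
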