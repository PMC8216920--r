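# Genotype file I/O: CSV dialect and GenePop (2/3-digit allele codes).

.metaCols <- c("id", "sex", "age_class", "role", "group", "country")

#' Read a multilocus genotype table
#'
#' Two dialects are supported.  The CSV dialect carries full metadata with
#' header \code{id,sex,age_class,role,group,country,<locus>.a1,<locus>.a2,...};
#' missing alleles are empty fields or 0.  The GenePop dialect uses 4-digit
#' (2 per allele) or 6-digit (3 per allele) codes with \code{0000}/\code{000000}
#' for missing; POP blocks map to group labels, and metadata absent from the
#' format (sex, age class, role, country) is filled with \code{unknown}/NA.
#'
#' @param path input file
#' @param dialect "csv" or "genepop"
#' @return validated \linkS4class{GenotypeTable}
#' @export
readGenotypes <- function(path, dialect = c("csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect, csv = .readGenoCsv(path), genepop = .readGenePop(path))
}

.parseAllele <- function(x, row, col) {
  x <- trimws(x)
  x[x == "" | x == "0"] <- NA
  bad <- !is.na(x) & !grepl("^[0-9]+$", x)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("malformed allele token '%s' at row %d, column %s",
                 x[i], row[which(bad)[1]], col))
  }
  as.integer(x)
}

.readGenoCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!all(.metaCols %in% names(df)))
    stop("CSV genotype file must start with columns ",
         paste(.metaCols, collapse = ","))
  acols <- setdiff(names(df), .metaCols)
  if (!all(grepl("\\.(a1|a2)$", acols)))
    stop("allele columns must be named <locus>.a1 / <locus>.a2")
  loci <- unique(sub("\\.(a1|a2)$", "", acols))
  if (anyDuplicated(df$id))
    stop("duplicate individual id: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  n <- nrow(df)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                     dimnames = list(df$id, loci))
  for (l in loci) {
    c1 <- paste0(l, ".a1"); c2 <- paste0(l, ".a2")
    if (!all(c(c1, c2) %in% names(df)))
      stop("locus ", l, " lacks one of its two allele columns")
    a1[, l] <- .parseAllele(df[[c1]], seq_len(n), c1)
    a2[, l] <- .parseAllele(df[[c2]], seq_len(n), c2)
  }
  meta <- df[.metaCols]
  meta$sex[is.na(meta$sex) | meta$sex == ""] <- "unknown"
  meta$age_class[is.na(meta$age_class) | meta$age_class == ""] <- "adult"
  for (cc in c("role", "group", "country"))
    meta[[cc]][meta[[cc]] %in% ""] <- NA_character_
  GenotypeTable(a1, a2, meta)
}

#' Write a genotype table
#'
#' @param table GenotypeTable
#' @param path output file
#' @param dialect "csv" (canonical, round-trips exactly) or "genepop"
#' @param digits allele-code width per allele for GenePop (2 or 3)
#' @export
writeGenotypes <- function(table, path, dialect = c("csv", "genepop"),
                           digits = 3) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") .writeGenoCsv(table, path)
  else .writeGenePop(table, path, digits)
  invisible(path)
}

.writeGenoCsv <- function(table, path) {
  loci <- lociNames(table)
  out <- table@meta
  for (l in loci) {
    out[[paste0(l, ".a1")]] <- ifelse(is.na(table@a1[, l]), "",
                                      table@a1[, l])
    out[[paste0(l, ".a2")]] <- ifelse(is.na(table@a2[, l]), "",
                                      table@a2[, l])
  }
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.readGenePop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("GenePop file too short")
  body <- lines[-1]                      # first line is a title comment
  popIdx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(popIdx)) stop("GenePop file has no POP line")
  locusPart <- body[seq_len(popIdx[1] - 1)]
  loci <- trimws(unlist(strsplit(locusPart, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); grp <- character()
  rows1 <- list(); rows2 <- list()
  popNames <- paste0("POP", seq_along(popIdx))
  bounds <- c(popIdx, length(body) + 1L)
  for (k in seq_along(popIdx)) {
    blk <- body[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    if (bounds[k] + 1L > bounds[k + 1L] - 1L) next
    for (ln in blk) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2)
        stop("malformed GenePop sample line (no comma): ", ln)
      id <- trimws(parts[1])
      codes <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                        "\\s+")[[1]]
      if (length(codes) != length(loci))
        stop(sprintf("individual %s: %d allele codes for %d loci",
                     id, length(codes), length(loci)))
      w <- nchar(codes)
      if (!all(w %in% c(4L, 6L)) || !all(grepl("^[0-9]+$", codes)))
        stop("malformed allele code for individual ", id, ": ",
             codes[which(!w %in% c(4L, 6L) | !grepl("^[0-9]+$", codes))[1]])
      half <- w / 2
      x1 <- as.integer(substr(codes, 1, half))
      x2 <- as.integer(substr(codes, half + 1, w))
      x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
      miss <- is.na(x1) | is.na(x2)      # half-typed treated as missing locus
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      ids <- c(ids, id); grp <- c(grp, popNames[k])
      rows1[[length(rows1) + 1L]] <- x1
      rows2[[length(rows2) + 1L]] <- x2
    }
  }
  if (anyDuplicated(ids)) stop("duplicate individual id in GenePop file")
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  GenotypeTable(a1, a2,
                data.frame(id = ids, sex = "unknown", age_class = "adult",
                           role = NA_character_, group = grp,
                           country = NA_character_,
                           stringsAsFactors = FALSE))
}

.writeGenePop <- function(table, path, digits = 3) {
  stopifnot(digits %in% c(2, 3))
  if (any(table@a2 >= 10^digits, na.rm = TRUE))
    stop("allele sizes too large for ", digits, "-digit GenePop codes")
  fmt <- function(m) {
    x <- sprintf(paste0("%0", digits, "d"), ifelse(is.na(m), 0L, m))
    matrix(x, nrow = nrow(m))
  }
  s1 <- fmt(table@a1); s2 <- fmt(table@a2)
  codes <- matrix(paste0(s1, s2), nrow = nInd(table))
  grp <- table@meta$group
  grp[is.na(grp)] <- "UNGROUPED"
  con <- file(path, "w"); on.exit(close(con))
  writeLines("exported genotypes", con)
  writeLines(lociNames(table), con)
  for (g in unique(grp)) {
    writeLines("POP", con)
    idx <- which(grp == g)
    writeLines(paste0(table@meta$id[idx], " , ",
                      apply(codes[idx, , drop = FALSE], 1, paste,
                            collapse = " ")), con)
  }
}
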