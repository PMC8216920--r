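# End-to-end pipeline: load -> filter -> frequencies/diversity ->
# relatedness -> kin tests -> parentage -> spatial -> proximity, writing
# per-stage TSV/JSON outputs and a run manifest.  The pipeline is a pure
# function of (inputs, config, seed): rerunning with the same config gives
# identical outputs.

#' Pipeline run configuration
#'
#' @param genotypes path to a genotype file
#' @param dialect genotype dialect ("csv" or "genepop")
#' @param locations optional locations CSV (group, lat, lon, country)
#' @param distances optional square distance CSV (km); overrides coordinates
#' @param scans optional scans CSV (focal, partner, category)
#' @param hours optional dyad hours CSV (id1, id2, hours)
#' @param estimator relatedness estimator for the analysis stages
#' @param minValidLoci individual inclusion threshold
#' @param minSharedLoci dyad definition threshold
#' @param nPerm permutation count for all tests
#' @param seed RNG seed (logged in the manifest)
#' @param parentage ParentageConfig
#' @param stages character vector of stages to run (subset of the default)
#' @param outDir output directory
#' @return list of class "RunConfig"
#' @export
runConfig <- function(genotypes, dialect = "csv", locations = NULL,
                      distances = NULL, scans = NULL, hours = NULL,
                      estimator = "QG", minValidLoci = 7,
                      minSharedLoci = 5, nPerm = 10000, seed = 1,
                      parentage = parentageConfig(),
                      stages = c("diversity", "relatedness", "kin",
                                 "parentage", "spatial", "proximity"),
                      outDir = "gorillakin_out") {
  structure(list(genotypes = genotypes, dialect = dialect,
                 locations = locations, distances = distances,
                 scans = scans, hours = hours, estimator = estimator,
                 minValidLoci = minValidLoci,
                 minSharedLoci = minSharedLoci, nPerm = nPerm,
                 seed = seed, parentage = parentage, stages = stages,
                 outDir = outDir),
            class = "RunConfig")
}

#' Read a RunConfig from a YAML or JSON file
#' @param path config file (.yaml/.yml needs the yaml package, else JSON)
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- do.call(parentageConfig, as.list(cfg$parentage))
  cfg$parentage <- NULL
  do.call(runConfig, c(cfg, list(parentage = pc)))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing per-stage TSV/JSON
#' outputs under \code{config$outDir} plus \code{manifest.json} recording
#' the seed, the config (with an md5 hash) and the package version.  A
#' stage failure aborts with an error naming the stage; outputs of earlier
#' stages are retained.
#'
#' @param config RunConfig
#' @return invisible list of stage results
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  out <- function(...) file.path(config$outDir, ...)
  # manifest first: config hash is over the serialised config file
  cfgPath <- out("config.json")
  cfgList <- unclass(config)
  cfgList$parentage <- unclass(cfgList$parentage)
  jsonlite::write_json(cfgList, cfgPath, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  tab <- stage("load", {
    t0 <- readGenotypes(config$genotypes, config$dialect)
    filterIndividuals(t0, config$minValidLoci)
  })
  res$table <- tab
  freqs <- stage("frequencies", alleleFrequencies(tab))
  adults <- tab@meta$id[tab@meta$age_class == "adult"]
  if ("diversity" %in% config$stages) {
    res$diversity <- stage("diversity", diversitySummary(freqs))
    writeDiversitySummary(res$diversity, out("diversity.tsv"))
    writeDiversitySummary(res$diversity, out("diversity.json"))
  }
  if ("relatedness" %in% config$stages) {
    res$relatedness <- stage("relatedness",
      relatednessMatrix(tab, freqs, config$estimator, subset = adults,
                        minSharedLoci = config$minSharedLoci,
                        pValues = TRUE, nPerm = min(config$nPerm, 1000),
                        seed = config$seed))
    writeRelatednessMatrix(res$relatedness, out("relatedness.tsv"))
  }
  if ("kin" %in% config$stages && !is.null(res$relatedness)) {
    res$kin <- stage("kin", {
      meta <- tab@meta
      fem <- meta$id[meta$sex == "female" & meta$age_class == "adult" &
                       !is.na(meta$group)]
      labels <- stats::setNames(meta$group[match(fem, meta$id)], fem)
      gt <- groupMeanRelatednessTest(res$relatedness, labels,
                                     nPerm = config$nPerm,
                                     seed = config$seed)
      sbOf <- stats::setNames(
        paste0(meta$group[match(fem, meta$id)], "_SB"), fem)
      males <- meta$id[meta$sex == "male" & meta$age_class == "adult"]
      sbOf <- sbOf[sbOf %in% males]
      ft <- if (length(sbOf))
        focalMaleRelatednessTest(res$relatedness, sbOf, males,
                                 nPerm = config$nPerm,
                                 seed = config$seed) else NULL
      list(groups = gt, focalMale = ft)
    })
    for (g in names(res$kin$groups))
      writePermutationResult(res$kin$groups[[g]],
                             out(sprintf("kin_group_%s.json", g)),
                             out(sprintf("kin_group_%s_hist.csv", g)))
    if (!is.null(res$kin$focalMale))
      writePermutationResult(res$kin$focalMale, out("kin_focal_male.json"))
  }
  if ("parentage" %in% config$stages) {
    res$parentage <- stage("parentage", {
      meta <- tab@meta
      off <- meta$id[meta$age_class == "immature"]
      mo <- meta$id[meta$sex == "female" & meta$age_class == "adult"]
      fa <- meta$id[meta$sex == "male" & meta$age_class == "adult"]
      if (length(off) && length(mo) && length(fa))
        assignParentage(tab, off, mo, fa, freqs, config$parentage,
                        seed = config$seed) else NULL
    })
    if (!is.null(res$parentage))
      utils::write.table(as.data.frame(res$parentage),
                         out("parentage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  if ("spatial" %in% config$stages) {
    res$spatial <- stage("spatial", {
      loc <- if (!is.null(config$locations))
        utils::read.csv(config$locations, stringsAsFactors = FALSE)
      else NULL
      ov <- if (!is.null(config$distances)) {
        m <- as.matrix(utils::read.csv(config$distances, row.names = 1,
                                       check.names = FALSE))
        colnames(m) <- rownames(m); m
      } else NULL
      if (is.null(loc) && is.null(ov)) NULL else {
        meta <- tab@meta
        grpOf <- stats::setNames(meta$group, meta$id)
        if (is.null(loc))
          loc <- data.frame(group = rownames(ov), lat = NA, lon = NA)
        D <- geographicDistanceMatrix(loc, override = ov)
        part <- grpOf[adults]
        part <- part[!is.na(part)]
        rst <- rstStatistic(tab, part, nPerm = config$nPerm,
                            seed = config$seed)
        ibd <- ibdRegression(rst$pairwise, D, nPerm = config$nPerm,
                             seed = config$seed)
        writeIbdResult(ibd, out("ibd.tsv"), out("ibd.json"))
        list(distances = D, rst = rst, ibd = ibd)
      }
    })
  }
  if ("proximity" %in% config$stages && !is.null(config$scans)) {
    res$proximity <- stage("proximity", {
      if (!file.exists(config$scans))
        stop("scans file not found: ", config$scans)
      scans <- utils::read.csv(config$scans, stringsAsFactors = FALSE)
      hours <- utils::read.csv(config$hours, stringsAsFactors = FALSE)
      dp <- buildDyadProximity(scans, hours)
      corr <- if (!is.null(res$relatedness))
        proximityRelatednessCorrelation(dp, res$relatedness) else NULL
      utils::write.table(as.data.frame(dp), out("proximity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(dyads = dp, correlation = corr)
    })
  }
  manifest <- list(
    package = "gorillakin",
    version = as.character(utils::packageVersion("gorillakin")),
    seed = config$seed,
    configHash = unname(tools::md5sum(cfgPath)),
    stages = config$stages,
    timestampFree = TRUE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  invisible(res)
}
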