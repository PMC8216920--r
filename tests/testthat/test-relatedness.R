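# Relatedness estimators, permutation significance, concordance.

test_that("QG and LR equal 1 for identical homozygotes and are symmetric", {
  f <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  a <- matrix(c(10L, 10L), 2, 1, dimnames = list(NULL, "L1"))
  tab <- GenotypeTable(a, a, data.frame(id = c("x", "y")))
  for (est in c("QG", "LR")) {
    v <- pairwiseRelatedness(tab, "x", "y", f, est, minSharedLoci = 1)
    expect_equal(v$value, 1)
  }
  # reciprocal averaging makes value(x,y) == value(y,x) exactly
  fr <- defaultFreqs()
  tab2 <- fixtureUnrelated(6, fr)
  for (est in c("QG", "LR", "LOISELLE")) {
    xy <- pairwiseRelatedness(tab2, c("I1", "I3"), c("I2", "I5"), fr, est)
    yx <- pairwiseRelatedness(tab2, c("I2", "I5"), c("I1", "I3"), fr, est)
    expect_equal(xy$value, yx$value)
  }
})

test_that("estimators recover expected values for known relationships", {
  cfg <- simulationConfig()
  fr <- defaultFreqs(99)
  expected <- c(PO = 0.5, HS = 0.25, U = 0)
  for (rel in names(expected)) {
    s <- simulateRelationshipDyads(cfg, rel, 1500, seed = 11, freqs = fr)
    for (est in c("QG", "LR")) {
      v <- pairwiseRelatedness(s$table, s$dyads$id1, s$dyads$id2, fr, est)
      expect_equal(mean(v$value, na.rm = TRUE), expected[[rel]],
                   tolerance = 0.04, ignore_attr = TRUE,
                   label = paste(rel, est))
    }
    vl <- pairwiseRelatedness(s$table, s$dyads$id1, s$dyads$id2, fr,
                              "LOISELLE")
    expect_equal(mean(vl$value, na.rm = TRUE), expected[[rel]] / 2,
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("relatedness matrix covers all unordered pairs and flags undefined ones", {
  fr <- defaultFreqs()
  tab <- fixtureUnrelated(22, fr)
  rm22 <- relatednessMatrix(tab, fr, "QG")
  expect_equal(nrow(estimates(rm22)), 231)   # 22 adults -> 231 pairs
  tab2 <- fixtureUnrelated(3, fr)
  # I3 typed at 3 loci only: pairs with I3 undefined at minSharedLoci 5
  tab2@a1[3, 4:10] <- tab2@a2[3, 4:10] <- NA_integer_
  rm3 <- relatednessMatrix(tab2, fr, "QG")
  e <- estimates(rm3)
  expect_equal(nrow(e), 3)
  expect_true(all(is.na(e$value[e$id1 == "I3" | e$id2 == "I3"])))
  expect_error(relatednessMatrix(tab2, fr, subset = "I1"), "at least 2")
  expect_error(pairwiseRelatedness(tab2, "I1", "I3", fr, "QG"),
               "undefined")
  M <- as.matrix(rm3)
  expect_true(isSymmetric(M))
  expect_true(all(is.na(diag(M))))
})

test_that("allele-permutation p-values flag clones and stay calibrated at the null median", {
  fr <- defaultFreqs(5)
  g <- gorillakin:::.simHweGenotypes(fr, 1)
  a1 <- rbind(g$a1, g$a1); a2 <- rbind(g$a2, g$a2)
  rownames(a1) <- rownames(a2) <- c("c1", "c2")
  clone <- GenotypeTable(a1, a2, data.frame(id = c("c1", "c2")))
  r <- pairSignificanceTest(clone, "c1", "c2", fr, "QG", nPerm = 1000,
                            seed = 3)
  expect_lte(r$p, 0.01)
  expect_warning(pairSignificanceTest(clone, "c1", "c2", fr, "QG",
                                      nPerm = 50, seed = 1), "coarse")
  # a pair sitting at the null median gets p near 0.5
  tabU <- fixtureUnrelated(2, fr)
  r2 <- pairSignificanceTest(tabU, "I1", "I2", fr, "QG", nPerm = 400,
                             seed = 9)
  null <- attr(r2, "null")
  med <- stats::median(null)
  expect_equal(mean(null >= med), 0.5, tolerance = 0.06)
})

test_that("permutation p-values are uniform for unrelated pairs", {
  fr <- defaultFreqs(6)
  set.seed(31)
  ps <- replicate(300, {
    tab <- fixtureUnrelated(2, fr)
    pairSignificanceTest(tab, "I1", "I2", fr, "QG", nPerm = 150)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("estimator concordance is 1 for affine copies and high across estimators", {
  fr <- defaultFreqs(8)
  cfg <- simulationConfig()
  # mixed-relationship dyad set
  parts <- lapply(c("PO", "HS", "U"), function(rel)
    simulateRelationshipDyads(cfg, rel, 60, seed = match(rel, c("PO", "HS", "U")),
                              freqs = fr))
  tabs <- lapply(seq_along(parts), function(k) {
    t <- parts[[k]]$table
    t@meta$id <- paste0("S", k, "_", t@meta$id)
    rownames(t@a1) <- rownames(t@a2) <- t@meta$id
    t
  })
  a1 <- do.call(rbind, lapply(tabs, function(t) t@a1))
  a2 <- do.call(rbind, lapply(tabs, function(t) t@a2))
  meta <- do.call(rbind, lapply(tabs, function(t) t@meta))
  big <- GenotypeTable(a1, a2, meta)
  id1 <- unlist(lapply(seq_along(parts), function(k)
    paste0("S", k, "_", parts[[k]]$dyads$id1)))
  id2 <- unlist(lapply(seq_along(parts), function(k)
    paste0("S", k, "_", parts[[k]]$dyads$id2)))
  mk <- function(est) {
    e <- pairwiseRelatedness(big, id1, id2, fr, est)
    e$p <- NA_real_
    new("RelatednessMatrix", estimates = e, estimator = est,
        ids = unique(c(id1, id2)), reference = "test")
  }
  qg <- mk("QG"); lr <- mk("LR")
  self <- estimatorConcordance(list(a = qg, b = qg))
  expect_equal(self$r, 1)
  aff <- qg
  aff@estimates$value <- 2 * aff@estimates$value + 0.1
  expect_equal(estimatorConcordance(list(qg, aff))$r, 1)
  cc <- estimatorConcordance(list(QG = qg, LR = lr))
  expect_gt(cc$r, 0.7)
  degen <- qg
  degen@estimates$value <- 0
  expect_error(estimatorConcordance(list(qg, degen)), "zero variance")
})
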