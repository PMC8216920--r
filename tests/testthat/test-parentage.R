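# Parentage LODs, delta-confidence simulation, assignment, relationship LRs.

test_that("LOD scores match closed-form worked examples", {
  cfg0 <- parentageConfig(errorRate = 0)
  # offspring AB, known mother AA, candidate father BB, p_B = 0.5 -> ln 2
  f <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  a1 <- matrix(c(10L, 10L, 11L), 3, 1,
               dimnames = list(NULL, "L1"))
  a2 <- matrix(c(11L, 10L, 11L), 3, 1,
               dimnames = list(NULL, "L1"))
  tab <- GenotypeTable(a1, a2, data.frame(id = c("off", "mom", "dad")))
  r <- parentageLod(tab, "off", "dad", f, knownOtherParent = "mom",
                    config = cfg0)
  expect_equal(r$lod, log(2))
  expect_equal(r$mismatches, 0)
  # offspring AA, single candidate AA, p_A = 0.25 -> ln 4
  f2 <- alleleFreqTable(list(L1 = c(`10` = 0.25, `11` = 0.75)))
  b <- matrix(c(10L, 10L), 2, 1, dimnames = list(NULL, "L1"))
  tab2 <- GenotypeTable(b, b, data.frame(id = c("o", "c")))
  r2 <- parentageLod(tab2, "o", "c", f2, config = cfg0)
  expect_equal(r2$lod, log(4))
  # candidate sharing no allele: one mismatch, -Inf LOD at e = 0
  c1 <- matrix(c(10L, 12L), 2, 1, dimnames = list(NULL, "L1"))
  c2 <- matrix(c(11L, 13L), 2, 1, dimnames = list(NULL, "L1"))
  f3 <- alleleFreqTable(list(L1 = c(`10` = .25, `11` = .25, `12` = .25,
                                    `13` = .25)))
  tab3 <- GenotypeTable(c1, c2, data.frame(id = c("o", "c")))
  r3 <- parentageLod(tab3, "o", "c", f3, config = cfg0)
  expect_equal(r3$mismatches, 1)
  expect_identical(r3$lod, -Inf)
  # with error > 0 the LOD is finite and negative
  r4 <- parentageLod(tab3, "o", "c", f3,
                     config = parentageConfig(errorRate = 0.01))
  expect_true(is.finite(r4$lod) && r4$lod < 0)
})

test_that("transmission distribution over offspring genotypes sums to one", {
  f <- alleleFreqTable(list(L1 = c(`10` = 0.2, `11` = 0.3, `12` = 0.5)))
  sizes <- c(10L, 11L, 12L)
  gts <- expand.grid(a = sizes, b = sizes)
  gts <- gts[gts$a <= gts$b, ]
  p <- f@freqs$L1
  po1 <- p[as.character(gts$a)]; po2 <- p[as.character(gts$b)]
  for (e in c(0, 0.01)) {
    for (par in list(c(10L, 10L), c(10L, 11L), c(11L, 12L))) {
      tot <- 0
      for (k in seq_len(nrow(gts))) {
        Tm <- gorillakin:::.ppair(gts$a[k], gts$b[k], par[1], par[2],
                                  10L, 12L)
        hwe <- gorillakin:::.phwe(po1[k], po2[k], gts$a[k] == gts$b[k])
        tot <- tot + (1 - e) * Tm + e * hwe
      }
      expect_equal(unname(tot), 1)
    }
  }
})

test_that("delta thresholds are seed-deterministic and collapse for uninformative panels", {
  fr <- defaultFreqs(21)
  cfg <- parentageConfig(nSim = 400, propSampled = 1)
  t1 <- simulateConfidenceThresholds(fr, 5, cfg, "single", seed = 42)
  t2 <- simulateConfidenceThresholds(fr, 5, cfg, "single", seed = 42)
  expect_identical(t1$strict, t2$strict)
  expect_identical(t1$relaxed, t2$relaxed)
  # informative panel, all candidates sampled, e = 0: >= 95% recovery
  cfg0 <- parentageConfig(errorRate = 0, propSampled = 1, nSim = 400)
  t3 <- simulateConfidenceThresholds(fr, 5, cfg0, "single", seed = 7)
  expect_gte(t3$successRate, 0.95)
  # monomorphic panel: success near chance, strict threshold infinite
  mono <- alleleFreqTable(rep(list(c(`10` = 1)), 3))
  ws <- capture_warnings(
    tm <- simulateConfidenceThresholds(mono, 4,
                                       parentageConfig(nSim = 300),
                                       "single", seed = 1))
  expect_match(ws, "unreachable", all = TRUE)
  expect_length(ws, 2)
  expect_identical(tm$strict, Inf)
  expect_lt(tm$successRate, 0.5)
})

test_that("assignParentage recovers true parents and reports incompatible candidates", {
  fr <- defaultFreqs(33)
  set.seed(10)
  mom <- gorillakin:::.simHweGenotypes(fr, 1)
  dad <- gorillakin:::.simHweGenotypes(fr, 1)
  kids <- gorillakin:::.simOffspringOf(
    list(a1 = mom$a1[rep(1, 4), ], a2 = mom$a2[rep(1, 4), ]),
    list(a1 = dad$a1[rep(1, 4), ], a2 = dad$a2[rep(1, 4), ]))
  others <- gorillakin:::.simHweGenotypes(fr, 6)
  ids <- c("mom", "dad", paste0("kid", 1:4), paste0("u", 1:6))
  a1 <- rbind(mom$a1, dad$a1, kids$a1, others$a1)
  a2 <- rbind(mom$a2, dad$a2, kids$a2, others$a2)
  rownames(a1) <- rownames(a2) <- ids
  sex <- c("female", "male", rep("unknown", 4),
           rep(c("female", "male"), 3))
  tab <- GenotypeTable(a1, a2, data.frame(id = ids, sex = sex))
  mothers <- c("mom", "u1", "u3", "u5")
  fathers <- c("dad", "u2", "u4", "u6")
  res <- assignParentage(tab, paste0("kid", 1:4), mothers, fathers, fr,
                         parentageConfig(nSim = 400, propSampled = 1,
                                         errorRate = 0.01), seed = 77)
  pair <- res[res$analysis == "pair", ]
  expect_equal(pair$mother, rep("mom", 4))
  expect_equal(pair$father, rep("dad", 4))
  expect_true(all(pair$mismatches == 0))
  expect_true(all(pair$confidence %in% c("strict", "relaxed")))
})

test_that("relationship LRs separate full sibs from unrelated pairs", {
  fr <- defaultFreqs(44)
  cfg <- simulationConfig()
  pc <- parentageConfig()
  fs <- simulateRelationshipDyads(cfg, "FS", 300, seed = 1, freqs = fr)
  lr <- relationshipLikelihoodRatios(fs$table, fs$dyads$id1, fs$dyads$id2,
                                     fr, pc)
  expect_true(all(lr$lr[lr$relationship == "U"] == 1))
  expect_gt(stats::median(lr$lr[lr$relationship == "FS"]), 10)
  un <- simulateRelationshipDyads(cfg, "U", 300, seed = 2, freqs = fr)
  lru <- relationshipLikelihoodRatios(un$table, un$dyads$id1,
                                      un$dyads$id2, fr, pc)
  expect_lt(mean(lru$lr[lru$relationship == "FS"] > 10), 0.05)
  # PO impossible when a locus shares no allele (e = 0)
  f1 <- alleleFreqTable(list(L1 = c(`10` = .25, `11` = .25, `12` = .25,
                                    `13` = .25)))
  a1 <- matrix(c(10L, 12L), 2, 1, dimnames = list(NULL, "L1"))
  a2 <- matrix(c(11L, 13L), 2, 1, dimnames = list(NULL, "L1"))
  tab <- GenotypeTable(a1, a2, data.frame(id = c("x", "y")))
  r <- relationshipLikelihoodRatios(tab, "x", "y", f1,
                                    parentageConfig(errorRate = 0,
                                                    minSharedLoci = 1))
  expect_equal(r$lr[r$relationship == "PO"], 0)
})

test_that("error injection produces mismatches at the expected per-locus rate", {
  fr <- defaultFreqs(55)
  cfg <- simulationConfig(mutationRate = 0)
  n <- 400
  mom <- gorillakin:::.simHweGenotypes(fr, n)
  dad <- gorillakin:::.simHweGenotypes(fr, n)
  set.seed(8)
  kid <- gorillakin:::.simOffspringOf(mom, dad)
  # no error: all trios Mendelian at every locus
  mm0 <- mapply(function(i) {
    sum(gorillakin:::.ppair(kid$a1[i, ], kid$a2[i, ], mom$a1[i, ],
                            mom$a2[i, ], dad$a1[i, ], dad$a2[i, ]) == 0)
  }, seq_len(n))
  expect_equal(sum(mm0), 0)
  # e = 0.1 on the offspring: fraction of incompatible loci tracks the
  # probability that an HWE replacement is incompatible with the true pair
  kidE <- gorillakin:::.injectHweError(kid, fr, 0.1)
  mmE <- mapply(function(i) {
    sum(gorillakin:::.ppair(kidE$a1[i, ], kidE$a2[i, ], mom$a1[i, ],
                            mom$a2[i, ], dad$a1[i, ], dad$a2[i, ]) == 0)
  }, seq_len(n))
  rate <- sum(mmE) / (n * 10)
  expect_gt(rate, 0.02); expect_lt(rate, 0.1)
})
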