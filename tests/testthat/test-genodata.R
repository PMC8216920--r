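# Genotype container, I/O, filtering, frequencies, diversity.

test_that("CSV genotype files round-trip exactly", {
  tab <- fixtureTable()
  p <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(tab, p, "csv")
  back <- readGenotypes(p, "csv")
  expect_identical(back@a1, tab@a1)
  expect_identical(back@a2, tab@a2)
  expect_identical(back@meta, tab@meta)
  # second round trip is byte-identical
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeGenotypes(back, p2, "csv")
  expect_identical(readLines(p), readLines(p2))
})

test_that("GenePop files parse to the same genotypes as equivalent CSV", {
  tab <- fixtureTable()
  p <- withr::local_tempfile(fileext = ".gen")
  writeGenotypes(tab, p, "genepop", digits = 2)
  back <- readGenotypes(p, "genepop")
  # ids and genotypes survive; POP blocks carry group structure
  expect_setequal(back@meta$id, tab@meta$id)
  i <- match(tab@meta$id, back@meta$id)
  expect_equal(unname(back@a1[i, ]), unname(tab@a1))
  expect_equal(unname(back@a2[i, ]), unname(tab@a2))
  expect_equal(length(unique(back@meta$group)),
               length(unique(tab@meta$group)))
  # 3-digit codes too
  p3 <- withr::local_tempfile(fileext = ".gen")
  writeGenotypes(tab, p3, "genepop", digits = 3)
  back3 <- readGenotypes(p3, "genepop")
  expect_equal(unname(back3@a1[match(tab@meta$id, back3@meta$id), ]),
               unname(tab@a1))
})

test_that("malformed inputs raise named parse/validation errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex,age_class,role,group,country,L1.a1,L1.a2",
               "x,male,adult,,,,ABC,10"), p)
  expect_error(readGenotypes(p, "csv"), "malformed allele token 'ABC'")
  writeLines(c("id,sex,age_class,role,group,country,L1.a1,L1.a2",
               "x,male,adult,,,,10,10", "x,male,adult,,,,11,11"), p)
  expect_error(readGenotypes(p, "csv"), "duplicate")
  expect_error(readGenotypes("/nonexistent/file.csv", "csv"), "not found")
  # class validity
  a <- matrix(5L, 1, 1, dimnames = list("x", "L1"))
  expect_error(new("GenotypeTable", a1 = a, a2 = matrix(NA_integer_, 1, 1,
                   dimnames = list("x", "L1")),
                   meta = fixtureTable()@meta[1, ]),
               "whole-locus")
})

test_that("locus filter keeps exactly individuals above the threshold and is idempotent", {
  f <- defaultFreqs()
  tab <- fixtureUnrelated(4, f)
  # knock out loci: I1 typed at 6/10, I2 at 7/10, I3 all, I4 none
  tab@a1[1, 1:4] <- tab@a2[1, 1:4] <- NA_integer_
  tab@a1[2, 1:3] <- tab@a2[2, 1:3] <- NA_integer_
  tab@a1[4, ] <- tab@a2[4, ] <- NA_integer_
  out <- suppressMessages(filterIndividuals(tab, 7))
  expect_setequal(out@meta$id, c("I2", "I3"))
  expect_equal(attr(out, "removed"), c("I1", "I4"))
  again <- filterIndividuals(out, 7)
  expect_identical(again@a1, out@a1)
  allMiss <- tab
  allMiss@a1[] <- NA_integer_; allMiss@a2[] <- NA_integer_
  expect_warning(suppressMessages(filterIndividuals(allMiss, 1)),
                 "all individuals removed")
})

test_that("allele frequencies are direct counts and respect the reference filter", {
  a1 <- matrix(c(10L, 10L), 2, 1, dimnames = list(NULL, "L1"))
  a2 <- matrix(c(10L, 11L), 2, 1, dimnames = list(NULL, "L1"))
  tab <- GenotypeTable(a1, a2, data.frame(id = c("A", "B")))
  f <- alleleFrequencies(tab)
  expect_equal(unname(f@freqs$L1), c(0.75, 0.25))
  expect_equal(unname(f@nGenes["L1"]), 4)
  # sums to one on random tables
  tab2 <- fixtureUnrelated(15, defaultFreqs(7))
  f2 <- alleleFrequencies(tab2)
  expect_true(all(abs(vapply(f2@freqs, sum, 1) - 1) < 1e-12))
  # reference filter shifts frequencies on a scripted family
  fam1 <- matrix(c(10L, rep(10L, 9)), 10, 1, dimnames = list(NULL, "L1"))
  fam2 <- matrix(c(11L, rep(10L, 9)), 10, 1, dimnames = list(NULL, "L1"))
  fam <- GenotypeTable(fam1, fam2, data.frame(
    id = sprintf("X%d", 1:10),
    age_class = c("adult", rep("immature", 9))))
  fAll <- alleleFrequencies(fam)
  fAd <- alleleFrequencies(fam, function(m) m$age_class == "adult")
  expect_gt(fAll@freqs$L1[["10"]], fAd@freqs$L1[["10"]])
  expect_error(alleleFrequencies(fam, function(m) rep(FALSE, nrow(m))),
               "empty")
})

test_that("diversity summary matches closed forms and PID multiplies over loci", {
  f1 <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  d1 <- diversitySummary(f1, "raw")
  expect_equal(d1$meanHe, 0.5)
  expect_equal(d1$pid, 0.375)
  # monomorphic locus contributes He 0 and PID factor 1
  f2 <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5),
                             L2 = c(`20` = 1)))
  d2 <- diversitySummary(f2, "raw")
  expect_equal(d2$perLocus$He[2], 0)
  expect_equal(d2$pid, 0.375)
  # appending a polymorphic locus strictly decreases PID
  f3 <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5),
                             L2 = c(`20` = 0.3, `21` = 0.7)))
  d3 <- diversitySummary(f3, "raw")
  expect_lt(d3$pid, d1$pid)
  expect_equal(d3$pid, prod(d3$perLocus$pidLocus))
  # He is invariant under relabeling and maximal at uniform frequencies
  fr <- alleleFreqTable(list(L1 = c(`30` = 0.5, `31` = 0.5)))
  expect_equal(diversitySummary(fr, "raw")$meanHe, d1$meanHe)
  fu <- alleleFreqTable(list(L1 = c(`10` = 0.25, `11` = 0.75)))
  expect_lt(diversitySummary(fu, "raw")$meanHe, 0.5)
  # unbiased correction uses typed gene count
  fn <- alleleFreqTable(list(L1 = c(`10` = 0.5, `11` = 0.5)), nGenes = 4)
  expect_equal(diversitySummary(fn, "unbiased")$meanHe, 0.5 * 4 / 3)
})
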