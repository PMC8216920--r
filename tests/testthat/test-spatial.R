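# Geographic distances, R_ST, isolation-by-distance regression.

test_that("geodesic distances match reference values and the override path wins", {
  loc <- data.frame(group = c("a", "b"), lat = c(0, 0), lon = c(0, 1))
  D <- geographicDistanceMatrix(loc)
  expect_equal(D["a", "b"], 111.195, tolerance = 1e-4)
  expect_equal(diag(D), c(a = 0, b = 0))
  # symmetry and zero diagonal on random coordinates
  set.seed(2)
  loc2 <- data.frame(group = paste0("g", 1:5),
                     lat = runif(5, -60, 60), lon = runif(5, -170, 170))
  D2 <- geographicDistanceMatrix(loc2)
  expect_true(isSymmetric(unname(D2)))
  expect_true(all(diag(D2) == 0))
  # triangle inequality for geodesic distances
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(D2[i, j], D2[i, k] + D2[k, j] + 1e-9)
  # identical coordinates -> 0 km
  loc3 <- data.frame(group = c("x", "y"), lat = c(10, 10), lon = c(3, 3))
  expect_equal(geographicDistanceMatrix(loc3)["x", "y"], 0)
  # override matrix is returned as-is
  ov <- matrix(c(0, 9.1, 9.1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(geographicDistanceMatrix(loc, override = ov)["a", "b"], 9.1)
  locNA <- data.frame(group = "z", lat = NA, lon = NA)
  expect_error(geographicDistanceMatrix(locNA), "missing coordinates")
})

test_that("R_ST is 0 for identical populations, 1 for fixed differences, and size-shift invariant", {
  fr <- defaultFreqs(71)
  set.seed(3)
  tab <- fixtureUnrelated(40, fr)
  part <- setNames(rep(c("A", "B"), each = 20), tab@meta$id)
  r <- rstStatistic(tab, part, nPerm = 200, seed = 5)
  expect_lt(abs(r$global$rst), 0.05)
  expect_gt(r$global$p, 0.05)
  # two populations fixed for different single alleles
  a1 <- matrix(c(rep(10L, 5), rep(20L, 5)), 10, 1,
               dimnames = list(NULL, "L1"))
  tf <- GenotypeTable(a1, a1, data.frame(id = paste0("J", 1:10)))
  pf <- setNames(rep(c("A", "B"), each = 5), paste0("J", 1:10))
  rf <- rstStatistic(tf, pf, nPerm = 100, seed = 1)
  expect_equal(rf$global$rst, 1)
  # invariance under global allele-size translation
  shifted <- tab
  shifted@a1 <- tab@a1 + 7L; shifted@a2 <- tab@a2 + 7L
  r2 <- rstStatistic(shifted, part, nPerm = 1, seed = 5)
  expect_equal(r2$global$rst, r$global$rst)
  # monomorphic-in-size panel is an error
  mono <- GenotypeTable(matrix(10L, 4, 1, dimnames = list(NULL, "L1")),
                        matrix(10L, 4, 1, dimnames = list(NULL, "L1")),
                        data.frame(id = paste0("m", 1:4)))
  expect_error(rstStatistic(mono,
                            setNames(rep(c("A", "B"), 2), paste0("m", 1:4)),
                            nPerm = 10),
               "undefined")
})

test_that("IBD regression recovers exact linear relationships and excludes R_ST = 1", {
  pops <- paste0("P", 1:4)
  D <- matrix(0, 4, 4, dimnames = list(pops, pops))
  D[upper.tri(D)] <- c(5, 10, 20, 15, 30, 40)
  D <- D + t(D)
  pw <- as.data.frame(t(utils::combn(pops, 2)), stringsAsFactors = FALSE)
  names(pw) <- c("pop1", "pop2")
  ratio <- 0.1 * log(D[cbind(pw$pop1, pw$pop2)])
  pw$rst <- ratio / (1 + ratio)
  fit <- ibdRegression(pw, D, nPerm = 100, seed = 3)
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  # equal rst at all distances -> slope 0
  pw0 <- pw; pw0$rst <- 0.2
  expect_equal(ibdRegression(pw0, D, nPerm = 50, seed = 1)$slope, 0)
  # rst = 1 rows are excluded with a warning
  pw1 <- pw; pw1$rst[1] <- 1
  expect_warning(f1 <- ibdRegression(pw1, D, nPerm = 50, seed = 1),
                 "R_ST = 1")
  expect_equal(nrow(f1$table), 5)
  expect_error(ibdRegression(pw[1, , drop = FALSE], D),
               "three populations")
  expect_error(ibdRegression(pw[1:2, ], D), "fewer than 3 usable pairs")
})

test_that("stepping-stone simulation yields significant positive IBD; merging identical populations is neutral", {
  g8 <- data.frame(group = paste0("G", 1:8),
                   country = rep(c("W", "E"), each = 4))
  cc <- simulationConfig(groups = g8, femalesPerGroup = 15,
                         immaturesPerGroup = 0, nSolitary = 2,
                         extragroupPaternityRate = 0,
                         femaleDispersalRate = 0.35,
                         nearestGroupProb = 0.95,
                         maleDispersalGlobal = 0.05,
                         backgroundImmigrationRate = 0,
                         generations = 25)
  hits <- 0
  for (i in 1:5) {
    sim <- simulatePopulation(cc, seed = 500 + i)
    meta <- sim$table@meta
    ad <- meta$id[meta$age_class == "adult"]
    part <- setNames(meta$group[match(ad, meta$id)], ad)
    rst <- rstStatistic(sim$table, part, nPerm = 1, seed = 1)
    ibd <- suppressWarnings(
      ibdRegression(rst$pairwise, sim$distKm, nPerm = 200,
                    seed = 600 + i))
    hits <- hits + (ibd$p < 0.05 && ibd$slope > 0)
  }
  expect_gte(hits, 3)
  # duplicating a population as two labels leaves global rst about equal
  fr <- defaultFreqs(72)
  set.seed(9)
  tab <- fixtureUnrelated(60, fr)
  ids <- tab@meta$id
  part2 <- setNames(rep(c("A", "B"), each = 30), ids)
  part3 <- setNames(rep(c("A1", "A2", "B"), each = 20), ids)
  part3[21:30] <- "A1"  # A1/A2 both drawn from the same HWE pool
  r2 <- rstStatistic(tab, part2, nPerm = 1, seed = 1)$global$rst
  r3 <- rstStatistic(tab, part3, nPerm = 1, seed = 1)$global$rst
  expect_equal(r2, r3, tolerance = 0.05)
})
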