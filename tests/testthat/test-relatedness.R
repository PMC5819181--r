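test_that("allele frequencies are counted per cohort locus", {
  gt <- toyGenotypes(list(i1 = list(c(1, 1)), i2 = list(c(1, 2))))
  fr <- alleleFrequencies(gt)
  expect_equal(unname(fr$freq$L1[c("1", "2")]), c(0.75, 0.25))
  expect_equal(sum(fr$freq$L1), 1)
  expect_equal(unname(fr$n["L1"]), 2L)
  expect_error(alleleFrequencies(gt, character(0)), "empty")
  # monomorphic locus retained with frequency 1
  gtm <- toyGenotypes(list(i1 = list(c(1, 1)), i2 = list(c(1, 1))))
  expect_equal(unname(alleleFrequencies(gtm)$freq$L1), 1)
})

test_that("simulated founder frequencies recover the generating draw", {
  ped <- data.frame(id = paste0("I", 1:1000), dam = NA_character_,
                    sire = NA_character_, day = 0L, sex = "F",
                    stringsAsFactors = FALSE)
  cfg <- simConfig(seed = 9, nLoci = 4, missingRate = 0)
  gt <- simulateGenotypes(ped, cfg)
  fr <- alleleFrequencies(gt)
  for (l in names(fr$freq)) {
    truth <- gt$founderFreqs[[l]]
    est <- fr$freq[[l]][names(truth)]
    est[is.na(est)] <- 0
    expect_lt(max(abs(est - truth)), 0.04)  # ~3.5 SE at n = 2000 genes
  }
})

test_that("pedigree expected r matches path counting", {
  ped <- data.frame(
    id = c("gd", "gs", "d1", "d2", "s0", "k1", "k2", "k3", "c1", "c2"),
    dam = c(NA, NA, "gd", NA, NA, "d1", "d1", "d2", "k1", "k2"),
    sire = c(NA, NA, "gs", NA, NA, "s0", "s0", "s0", NA, NA),
    day = c(0, 0, 100, 100, 0, 200, 200, 200, 300, 300),
    sex = c("F", "M", "F", "F", "M", "F", "F", "F", "F", "F"),
    stringsAsFactors = FALSE)
  r <- pedigreeExpectedR(ped, data.frame(
    id1 = c("k1", "k1", "d1", "k1", "c1"),
    id2 = c("k2", "k3", "k1", "s0", "c2")))
  # full sibs, paternal half sibs, parent-offspring twice, first cousins
  expect_equal(r$expectedR, c(0.5, 0.25, 0.5, 0.5, 0.125), tolerance = 1e-12)
  expect_equal(r$class, c("full-sib", "half-sib", "parent-offspring",
                          "parent-offspring", "other"))
  expect_error(pedigreeExpectedR(ped, data.frame(id1 = "k1", id2 = "nope")),
               "not present")
})

test_that("expected r agrees with a gene-dropping oracle", {
  ped <- data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g"),
    dam = c(NA, NA, "a", "a", NA, "c", "d"),
    sire = c(NA, NA, "b", "b", NA, "e", "e"),
    day = c(0, 0, 100, 100, 0, 200, 200),
    sex = c("F", "M", "F", "F", "M", "F", "F"), stringsAsFactors = FALSE)
  set.seed(99)
  for (dy in list(c("f", "g"), c("c", "f"), c("a", "g"))) {
    exp_r <- pedigreeExpectedR(ped, data.frame(id1 = dy[1], id2 = dy[2]))$expectedR
    drop_r <- geneDrop(ped, dy[1], dy[2], nDrop = 10000)
    # binomial-scale Monte Carlo error on 10,000 drops
    expect_lt(abs(exp_r - drop_r), 0.02)
  }
})

test_that("Queller-Goodnight matches the hand-evaluated toy", {
  gt <- toyGenotypes(list(x = list(c(1, 2), c(1, 1), c(2, 3)),
                          y = list(c(1, 3), c(1, 2), c(4, 5))))
  fr <- toyFreqs(list(L1 = c(`1` = .4, `2` = .3, `3` = .3),
                      L2 = c(`1` = .5, `2` = .5),
                      L3 = c(`2` = .2, `3` = .2, `4` = .3, `5` = .3)))
  est <- quellerGoodnightR(gt, data.frame(id1 = "x", id2 = "y"), fr)
  # frozen value from manual per-locus evaluation of the ratio-of-sums
  # formula: (-0.6/1.9 + -0.8/0.7) / 2
  expect_equal(est$rhat, -0.72932331, tolerance = 1e-7)
  expect_equal(est$lociUsed, 3L)
})

test_that("dyads sharing no alleles get negative estimates", {
  gt <- toyGenotypes(list(u = list(c(1, 2), c(1, 1)),
                          v = list(c(3, 4), c(4, 4))))
  fr <- toyFreqs(list(L1 = c(`1` = .25, `2` = .25, `3` = .25, `4` = .25),
                      L2 = c(`1` = .3, `3` = .3, `4` = .4)))
  dy <- data.frame(id1 = "u", id2 = "v")
  expect_lt(quellerGoodnightR(gt, dy, fr)$rhat, 0)
  expect_lt(wangR(gt, dy, fr)$rhat, 0)
})

test_that("identical heterozygotes with rare alleles approach r = 1", {
  eps <- 1e-4
  common <- 1 - 2 * eps
  gt <- toyGenotypes(rep(list(lapply(1:10, function(l) c(1, 2))), 2) |>
                       setNames(c("x", "y")))
  fr <- toyFreqs(setNames(lapply(1:10, function(l)
    c(`1` = eps, `2` = eps, `3` = common)), paste0("L", 1:10)))
  expect_equal(quellerGoodnightR(gt, data.frame(id1 = "x", id2 = "y"),
                                 fr)$rhat, 1, tolerance = 1e-3)
})

test_that("estimators are symmetric and invariant to allele relabeling", {
  pan <- simulateDyadPanel(nPerClass = 40, nLoci = 10, seed = 2)
  dy <- pan$dyads$`full-sib`
  rev <- data.frame(id1 = dy$id2, id2 = dy$id1)
  expect_equal(wangR(pan$genotypes, dy, pan$freqs)$rhat,
               wangR(pan$genotypes, rev, pan$freqs)$rhat)
  expect_equal(quellerGoodnightR(pan$genotypes, dy, pan$freqs)$rhat,
               quellerGoodnightR(pan$genotypes, rev, pan$freqs)$rhat)
  # relabel alleles with a fixed permutation at every locus
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  gt2 <- pan$genotypes
  gt2$a1[] <- perm[gt2$a1]; gt2$a2[] <- perm[gt2$a2]
  gt2 <- genotypeTable(gt2$a1, gt2$a2)
  fr2 <- pan$freqs
  for (l in seq_along(fr2$freq))
    names(fr2$freq[[l]]) <- as.character(perm[as.integer(names(fr2$freq[[l]]))])
  expect_equal(wangR(gt2, dy, fr2)$rhat,
               wangR(pan$genotypes, dy, pan$freqs)$rhat, tolerance = 1e-12)
})

test_that("Wang is unbiased per pedigree class", {
  pan <- simulateDyadPanel(nPerClass = 300, seed = 31)
  expected <- c(`full-sib` = 0.5, `parent-offspring` = 0.5,
                `half-sib` = 0.25, unrelated = 0)
  for (cl in names(expected)) {
    est <- wangR(pan$genotypes, pan$dyads[[cl]], pan$freqs)$rhat
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - expected[[cl]]), 3 * mcse + 0.01)
  }
})

test_that("more loci reduce estimator variance", {
  p5 <- simulateDyadPanel(nPerClass = 250, nLoci = 5, seed = 12)
  p25 <- simulateDyadPanel(nPerClass = 250, nLoci = 25, seed = 12)
  v5 <- var(wangR(p5$genotypes, p5$dyads$unrelated, p5$freqs)$rhat)
  v25 <- var(wangR(p25$genotypes, p25$dyads$unrelated, p25$freqs)$rhat)
  expect_lt(v25, v5)
})

test_that("missing data are skipped locus-wise, flagged when too sparse", {
  pan <- simulateDyadPanel(nPerClass = 5, nLoci = 10, seed = 3)
  gt <- pan$genotypes
  gt$a1["A1", 1:9] <- NA; gt$a2["A1", 1:9] <- NA
  est <- wangR(gt, data.frame(id1 = "A1", id2 = "B1"), pan$freqs)
  expect_equal(est$lociUsed, 1L)
  expect_true(is.na(est$rhat))
  gt$a1["A2", 1:5] <- NA; gt$a2["A2", 1:5] <- NA
  est2 <- wangR(gt, data.frame(id1 = "A2", id2 = "B2"), pan$freqs)
  expect_equal(est2$lociUsed, 5L)
  expect_false(is.na(est2$rhat))
})

test_that("the bias-corrected and leave-dyad-out toggles stay consistent", {
  pan <- simulateDyadPanel(nPerClass = 50, nLoci = 10, seed = 8)
  dy <- head(pan$dyads$`full-sib`, 5)
  base <- wangR(pan$genotypes, dy, pan$freqs)$rhat
  bc <- wangR(pan$genotypes, dy, pan$freqs, biasCorrected = TRUE)$rhat
  ldo <- wangR(pan$genotypes, dy, pan$freqs, excludeDyad = TRUE)$rhat
  # large cohort: all three variants nearly coincide
  expect_lt(max(abs(base - bc)), 0.05)
  expect_lt(max(abs(base - ldo)), 0.05)
})

test_that("the calibration procedure ranks estimators by correlation", {
  col <- defaultColony()
  ped <- colonyPedigree(col); gt <- colonyGenotypes(col)
  perfect <- function(genotypes, dyads, freqs) {
    r <- pedigreeExpectedR(ped, dyads)
    data.frame(id1 = r$id1, id2 = r$id2, estimator = "perfect",
               rhat = unname(nestshare:::expectedRByClass[r$class]))
  }
  constant <- function(genotypes, dyads, freqs)
    data.frame(id1 = dyads[[1]], id2 = dyads[[2]], estimator = "const",
               rhat = 0.3)
  cal <- estimatorCalibration(ped, gt,
                              estimators = list(perfect = perfect,
                                                wang = wangR,
                                                const = constant),
                              seed = 17)
  expect_equal(cal$correlation[cal$estimator == "perfect"], 1)
  expect_true(is.na(cal$correlation[cal$estimator == "const"]))
  wangCor <- cal$correlation[cal$estimator == "wang"]
  expect_gt(wangCor, 0.7)
  expect_equal(cal$estimator[1], "perfect")
  # dyad draws are seeded
  cal2 <- estimatorCalibration(ped, gt, seed = 17)
  expect_equal(attr(cal2, "dyads")$id1,
               attr(estimatorCalibration(ped, gt, seed = 17), "dyads")$id1)
  # insufficient dyads in a class fail loudly
  tiny <- ped[1:10, ]
  expect_error(estimatorCalibration(tiny, gt, seed = 1), "dyads")
})
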