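test_that("seeded generators are deterministic", {
  cfg <- smallConfig(seed = 11)
  p1 <- simulatePedigree(cfg)
  p2 <- simulatePedigree(cfg)
  expect_identical(p1, p2)
  g1 <- simulateGenotypes(p1, cfg)
  g2 <- simulateGenotypes(p2, cfg)
  expect_identical(g1$a1, g2$a1)
  s1 <- simulateSettlement(p1, cfg)
  s2 <- simulateSettlement(p1, cfg)
  expect_identical(s1$events, s2$events)
  b1 <- simulateBirthsDecisions(p1, s1, cfg)
  b2 <- simulateBirthsDecisions(p1, s1, cfg)
  expect_identical(b1$births, b2$births)
})

test_that("pedigree supplies the calibration dyad classes", {
  ped <- colonyPedigree(defaultColony())
  for (cls in c("full-sib", "parent-offspring", "half-sib", "unrelated")) {
    d <- samplePedigreeDyads(ped, cls, 50, seed = 1)
    expect_equal(nrow(d), 50)
    got <- pedigreeExpectedR(ped, d)
    expect_true(all(got$class == cls))
  }
  # overlapping generations and two year cohorts
  expect_gt(length(unique(ped$gen)), 2)
  yrs <- unique(2008 + ped$day %/% 365)
  expect_gte(length(yrs), 2)
  # an infeasible configuration fails naming the missing class
  expect_error(simulatePedigree(simConfig(seed = 1, nFounders = 4,
                                          nGenerations = 1,
                                          littersPerFemale = 1)),
               "dyads")
})

test_that("full siblings are classified as such", {
  ped <- data.frame(id = c("d", "s", "k1", "k2"),
                    dam = c(NA, NA, "d", "d"), sire = c(NA, NA, "s", "s"),
                    day = c(0, 0, 100, 100), sex = c("F", "M", "F", "F"),
                    stringsAsFactors = FALSE)
  got <- pedigreeExpectedR(ped, data.frame(id1 = "k1", id2 = "k2"))
  expect_equal(got$class, "full-sib")
  expect_equal(got$expectedR, 0.5)
})

test_that("genotype transmission is Mendelian", {
  # forced outcome: dam AA x sire AA -> offspring AA
  ped <- data.frame(id = c("d", "s", "k"), dam = c(NA, NA, "d"),
                    sire = c(NA, NA, "s"), day = c(0, 0, 100),
                    sex = c("F", "M", "F"), stringsAsFactors = FALSE)
  for (seed in 1:10) {
    cfg <- simConfig(seed = seed, nLoci = 3, allelesPerLocus = 2,
                     missingRate = 0)
    gt <- simulateGenotypes(ped, cfg)
    hom <- gt$a1["d", ] == gt$a2["d", ] & gt$a1["s", ] == gt$a2["s", ] &
      gt$a1["d", ] == gt$a1["s", ]
    if (any(hom)) {
      expect_equal(gt$a1["k", hom], gt$a1["d", hom])
      expect_equal(gt$a2["k", hom], gt$a1["d", hom])
    }
  }
  # distributional outcome: dam AB x sire CD -> four offspring genotypes at
  # frequency ~ 1/4 each over 10,000 offspring
  n <- 10000L
  bigPed <- rbind(ped[1:2, ],
                  data.frame(id = paste0("k", seq_len(n)), dam = "d",
                             sire = "s", day = 100, sex = "F",
                             stringsAsFactors = FALSE))
  gt <- NULL
  for (seed in 1:30) {
    cand <- simulateGenotypes(bigPed, simConfig(seed = seed, nLoci = 1,
                                                allelesPerLocus = 8,
                                                missingRate = 0))
    distinct <- length(unique(c(cand$a1[1:2, 1], cand$a2[1:2, 1]))) == 4L
    if (distinct) { gt <- cand; break }
  }
  expect_false(is.null(gt))
  kid <- paste(gt$a1[-(1:2), 1], gt$a2[-(1:2), 1])
  tab <- table(kid) / n
  expect_equal(length(tab), 4L)
  expect_true(all(abs(tab - 0.25) < 0.02))
})

test_that("stays never overlap and exits exceed entries", {
  ev <- colonyEvents(defaultColony())
  expect_true(all(ev$exit_s > ev$entry_s))
  dt <- data.table::as.data.table(ev)[order(tag, entry_s)]
  ok <- dt[, .N == 1L || all(entry_s[-1] >= exit_s[-.N]), by = tag]$V1
  expect_true(all(ok))
})

test_that("daughters settle near their mothers at the dispersal scale", {
  cfg <- smallConfig(seed = 21, dispersalMeanCm = 50)
  ped <- simulatePedigree(cfg)
  st <- simulateSettlement(ped, cfg)
  h <- st$homes
  dam <- ped$dam[match(h$id, ped$id)]
  ok <- !is.na(dam) & dam %in% h$id
  d <- sqrt((h$x[ok] - h$x[match(dam[ok], h$id)])^2 +
              (h$y[ok] - h$y[match(dam[ok], h$id)])^2)
  expect_gt(length(d), 50)
  # barn clipping truncates the exponential tail slightly
  expect_gt(mean(d), 30)
  expect_lt(mean(d), 70)
})

test_that("random-box decisions make communal frequency track occupancy", {
  dec <- simTruth(defaultColony())$decisions
  binomSe <- sqrt(sum(dec$P * (1 - dec$P))) / nrow(dec)
  expect_lt(abs(mean(dec$y) - mean(dec$P)), 4 * binomSe)
})

test_that("power mode honours the degenerate occupancy cases", {
  cfg <- smallConfig(seed = 31, decisionMode = "power", powerA = 2)
  col <- simulateColony(cfg)
  dec <- simTruth(col)$decisions
  expect_true(all(dec$y[dec$P == 0] == 0))
  expect_true(all(dec$y[dec$P == 1] == 1))
})

test_that("preference mode records coherent ground truth", {
  cfg <- smallConfig(seed = 41, decisionMode = "preference")
  col <- simulateColony(cfg)
  dec <- simTruth(col)$decisions
  op <- simTruth(col)$options
  expect_true(all(dec$y[dec$nOptions == 0] == 0))
  chosen <- op[op$chosen, ]
  expect_true(all(chosen$eventId %in% dec$eventId[dec$y == 1]))
  expect_identical(dec$partner[match(chosen$eventId, dec$eventId)],
                   chosen$optionId)
})

test_that("the default colony reproduces the study's structure", {
  dec <- simTruth(defaultColony())$decisions
  expect_gt(nrow(dec), 250)            # ~300 litters over two years
  expect_gt(mean(dec$nRegular), 4.2)   # ~5 regularly used boxes
  expect_lt(mean(dec$nRegular), 6.2)
  withOpt <- dec$nOptions[dec$nOptions > 0]
  expect_gt(mean(withOpt), 2)          # a handful of options per decision
  expect_lt(mean(withOpt), 6)
  expect_true(max(dec$nOptions) <= 15)
})
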