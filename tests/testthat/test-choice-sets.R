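test_that("litters are classified into solitary, communal and cryptic nests", {
  births <- data.frame(mother = c("A", "B", "C", "D", "E"),
                       day = c(10, 13, 40, 40, 80),
                       box = c(1, 1, 2, 2, 1))
  cls <- classifyLitters(births)
  expect_equal(cls$status, c("communal", "communal", "communal", "communal",
                             "solitary"))
  expect_equal(cls$group[1], cls$group[2])
  expect_false(cls$group[1] == cls$group[5])   # 70 d gap splits the box-1 nests
  expect_false(any(cls$cryptic[1:2]))          # 3 d apart: later mother joins
  expect_true(all(cls$cryptic[3:4]))           # same day, same box
  expect_equal(cls$joinOrder[1:2], c(1, 2))
})

test_that("cryptic resolution is seeded and symmetric", {
  r1 <- resolveCryptic(c("A", "B"), seed = 10)
  r2 <- resolveCryptic(c("A", "B"), seed = 10)
  expect_identical(r1, r2)
  expect_setequal(c(r1$focal, r1$residents), c("A", "B"))
  expect_warning(r3 <- resolveCryptic(c("A", "B", "C"), seed = 1), "cryptic")
  expect_length(r3$residents, 2L)
})

test_that("occupancy proportion counts boxes, not litters", {
  births <- data.frame(mother = c("A", "B", "C"), day = c(95, 97, 98),
                       box = c(1, 1, 2))
  # 5 regular boxes, two occupied -> P = 0.4 (the worked example)
  expect_equal(occupancyProportion("Z", 100, 1:5, births), 0.4)
  expect_equal(occupancyProportion("Z", 100, 3:5, births[3, ]), 0)
  expect_equal(occupancyProportion("Z", 100, 1:2, births), 1)
  expect_error(occupancyProportion("Z", 100, integer(0), births), "empty")
})

test_that("option females respect the 16-day window and the home area", {
  births <- data.frame(mother = c("A", "B", "C", "D"),
                       day = c(83, 90, 99, 100), box = c(1, 2, 1, 3))
  # focal at day 100 with home boxes {1, 2}: A is 17 d old (weaned), B and C
  # qualify, D is same-day in another box
  op <- optionFemales("Z", 100, focalBox = 1, regularBoxes = c(1, 2),
                      births = births)
  expect_setequal(op$optionId, c("B", "C"))
  expect_equal(op$pupAge[op$optionId == "B"], 10)
  # a litter 16 d old still qualifies
  op2 <- optionFemales("Z", 99, focalBox = 1, regularBoxes = c(1, 2),
                       births = births)
  expect_true("A" %in% op2$optionId)
})

test_that("the ten-birth fixture matches the hand-computed choice sets", {
  ch <- buildChoiceTable(toyColony(), seed = 3)
  ev <- ch$events
  expect_equal(nrow(ev), 7L)
  expect_equal(nrow(ch$excluded), 3L)
  expect_setequal(ch$excluded$litter, c(1L, 2L, 8L))
  expect_equal(nrow(ev) + nrow(ch$excluded), nrow(colonyBirths(toyColony())))

  expectOpts <- list(`3` = "F1", `4` = "F2", `5` = "F3", `6` = c("F3", "F4"),
                     `7` = "F4", `9` = "F7", `10` = "F6")
  expectP <- c(`3` = 1/2, `4` = 1/2, `5` = 1/2, `6` = 1/3, `7` = 1/2,
               `9` = 1/2, `10` = 1/2)
  expectY <- c(`3` = 0, `4` = 0, `5` = 1, `6` = 0, `7` = 1, `9` = 0, `10` = 0)
  for (e in ev$eventId) {
    key <- as.character(e)
    op <- ch$options[ch$options$eventId == e, ]
    expect_setequal(op$optionId, expectOpts[[key]])
    expect_equal(ev$P[ev$eventId == e], expectP[[key]])
    expect_equal(ev$y[ev$eventId == e], expectY[[key]])
  }
  expect_equal(ev$chosenOption[ev$eventId == 5], "F3")
  expect_equal(ev$chosenOption[ev$eventId == 7], "F4")
  # brute-force filter oracle over all births for every event
  births <- colonyBirths(toyColony())
  for (e in ev$eventId) {
    focal <- births$mother[e]; d <- births$day[e]
    reg <- toyHomeBoxes[[focal]]
    oracle <- births$mother[births$box %in% reg & births$mother != focal &
                              births$day >= d - 16 & births$day <= d - 1]
    expect_setequal(ch$options$optionId[ch$options$eventId == e], oracle)
  }
  # chosen option is always a member of the option list
  for (e in ev$eventId[ev$y == 1]) {
    expect_true(ev$chosenOption[ev$eventId == e] %in%
                  ch$options$optionId[ch$options$eventId == e])
  }
})

test_that("option covariates on the fixture are as constructed", {
  ch <- buildChoiceTable(toyColony(), seed = 3)
  op <- ch$options
  # pup ages: event 6 has the 16 d boundary litter and an 8 d litter
  expect_setequal(op$pupAge[op$eventId == 6], c(16, 8))
  # shared regular boxes: F4 (event 5 focal, home {4,1}) with option F3
  # (home {3,4}) share exactly box 4
  expect_equal(op$sharedBoxes[op$eventId == 5], 1)
  # litter-size difference: |3 - 5| for event 5 (F4 size 3, F3 size 5)
  expect_equal(op$litterDiff[op$eventId == 5], 2)
  # option litter of event 7 (B5, already joined B4) is not solitary
  expect_false(op$optionSolitary[op$eventId == 7])
  # option litter of event 5 (B4, alone in box 4 then) is solitary
  expect_true(op$optionSolitary[op$eventId == 5])
})

test_that("cryptic nests designate one focal and average joined residents", {
  ch <- buildChoiceTable(crypticColony(), seed = 21)
  ev <- ch$events
  expect_equal(nrow(ev), 2L)   # one of F1/F2 plus the joiner F3
  expect_equal(sum(ch$excluded$reason == "cryptic_resident"), 1L)
  founder <- ev[ev$day == 50, ]
  expect_true(founder$cryptic)
  expect_equal(founder$y, 1L)
  # the designated focal's chosen option is her same-day partner
  expect_true(founder$chosenOption %in% c("F1", "F2"))
  expect_false(founder$chosenOption == founder$mother)
  # the joiner gets one averaged pseudo-option in place of the two residents
  joiner <- ev[ev$day == 55, ]
  opJ <- ch$options[ch$options$eventId == joiner$eventId, ]
  expect_equal(nrow(opJ), 1L)
  expect_match(opJ$optionId, "^cryptic:")
  gt <- colonyGenotypes(crypticColony())
  fr <- alleleFrequencies(gt)
  r12 <- wangR(gt, data.frame(id1 = "F3", id2 = c("F1", "F2")), fr)$rhat
  expect_equal(opJ$rhat, mean(r12))
  expect_equal(opJ$pupAge, 5)
  # determinism of the designation
  ch2 <- buildChoiceTable(crypticColony(), seed = 21)
  expect_identical(ch$events$mother, ch2$events$mother)
})

test_that("covariate scaling round-trips", {
  ch <- buildChoiceTable(toyColony(), seed = 3)
  sc <- scaleCovariates(ch)
  expect_false(is.null(sc$scaling))
  back <- unscaleCovariates(sc)
  for (v in sc$scaling$var)
    expect_equal(back$options[[v]], ch$options[[v]], tolerance = 1e-12)
})

test_that("events lacking genotyped options are flagged incomplete", {
  col <- toyColony()
  gt <- colonyGenotypes(col)
  gt$a1[c("F1"), ] <- NA; gt$a2[c("F1"), ] <- NA
  col2 <- ColonyDataset(events = colonyEvents(col), births = colonyBirths(col),
                        pedigree = colonyPedigree(col), genotypes = gt,
                        layout = colonyLayout(col), config = col@config)
  ch <- buildChoiceTable(col2, seed = 3)
  # F1 is the option of event 3, so that event is incomplete
  expect_true(ch$events$incomplete[ch$events$eventId == 3])
  expect_false(ch$events$incomplete[ch$events$eventId == 4])
})
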