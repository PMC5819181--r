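#' Classify litters into solitary, communal and cryptic nests
#'
#' Litters sharing a nest box with an age gap of at most `gapDays` days are
#' grouped into one communal nest (1 litter = solitary, >= 2 litters =
#' communal). Two litters born on the same day in the same box form a cryptic
#' communal nest: the joining order is unobservable. For ordinary communal
#' nests the later mother is the joiner (the decision is made by the pregnant
#' female about to give birth).
#'
#' @param births birth table data.frame(mother, day, box, ...).
#' @param gapDays maximal age gap for pooling (default 16).
#' @return data.frame(litter, mother, day, box, group, groupSize, status,
#'   joinOrder, cryptic) with one row per litter; `status` is `"solitary"` or
#'   `"communal"`; `joinOrder` ranks litters within a nest group by birth day
#'   (ties share a rank).
#' @export
classifyLitters <- function(births, gapDays = 16) {
  n <- nrow(births)
  out <- data.frame(litter = seq_len(n), mother = births$mother,
                    day = births$day, box = births$box,
                    stringsAsFactors = FALSE)
  o <- order(births$box, births$day)
  grp <- integer(n); gid <- 0L
  lastBox <- NA_integer_; lastDay <- NA_integer_
  for (k in o) {
    if (is.na(lastBox) || births$box[k] != lastBox ||
        births$day[k] - lastDay > gapDays) gid <- gid + 1L
    grp[k] <- gid
    lastBox <- births$box[k]; lastDay <- births$day[k]
  }
  out$group <- grp
  sz <- table(grp)
  out$groupSize <- as.integer(sz[as.character(grp)])
  out$status <- ifelse(out$groupSize > 1L, "communal", "solitary")
  out$joinOrder <- stats::ave(out$day, out$group,
                              FUN = function(d) rank(d, ties.method = "min"))
  sameDay <- stats::ave(out$day, out$group, FUN = function(d)
    as.integer(duplicated(d) | duplicated(d, fromLast = TRUE)))
  out$cryptic <- out$groupSize > 1L & sameDay == 1L
  out
}

#' Resolve a cryptic communal nest
#'
#' When two females gave birth on the same day in the same box, one of them
#' is designated the focal female uniformly at random (seeded, so the
#' designation is reproducible); all dyadic attributes between the two are
#' symmetric, so the covariates are identical whichever is focal. Groups of
#' more than two same-day litters are resolved the same way with a warning.
#'
#' @param mothers character vector of the same-day mothers (length >= 2).
#' @param seed integer seed.
#' @return list with `focal` (the designated decision-maker) and `residents`
#'   (the remaining mothers, treated as already nesting).
#' @export
resolveCryptic <- function(mothers, seed = NULL) {
  stopifnot(length(mothers) >= 2L)
  if (length(mothers) > 2L)
    warning("cryptic group of ", length(mothers),
            " same-day litters; resolving by random focal designation")
  withSeed(seed, {
    focal <- sample(mothers, 1L)
    list(focal = focal, residents = setdiff(mothers, focal))
  })
}

#' Option females for a focal birth
#'
#' Options are the mothers of litters born within the closed window
#' `[focal - 16 d, focal]` whose nest box lies in the focal female's regular
#' boxes (shared home area requirement). Same-day litters qualify only in the
#' focal's own box (the cryptic case); pups older than 16 days at the focal
#' birth are weaned and excluded.
#'
#' @param focalMother,focalDay,focalBox focal female id, birth day, and her
#'   chosen box (`NA` allowed; only used for same-day cryptic inclusion).
#' @param regularBoxes the focal's regular boxes.
#' @param births birth table.
#' @param optionWindowDays option window length (default 16).
#' @return data.frame(optionId, litter, day, box, pupAge) of qualifying
#'   litters (possibly empty).
#' @export
optionFemales <- function(focalMother, focalDay, focalBox, regularBoxes,
                          births, optionWindowDays = 16) {
  idx <- which(births$box %in% regularBoxes &
                 births$mother != focalMother &
                 births$day >= focalDay - optionWindowDays &
                 (births$day < focalDay |
                    (births$day == focalDay & !is.na(focalBox) &
                       births$box == focalBox)))
  data.frame(optionId = births$mother[idx], litter = idx,
             day = births$day[idx], box = births$box[idx],
             pupAge = focalDay - births$day[idx], stringsAsFactors = FALSE)
}

#' Occupancy proportion P of a focal home area
#'
#' The number of regular boxes that already contained one or several litters
#' born during the 16 days before the focal birth, divided by the number of
#' regular boxes. Boxes are counted, not litters.
#'
#' @inheritParams optionFemales
#' @return P in [0, 1].
#' @export
occupancyProportion <- function(focalMother, focalDay, regularBoxes, births,
                                optionWindowDays = 16) {
  if (!length(regularBoxes)) stop("empty home area: P undefined")
  occ <- unique(births$box[births$box %in% regularBoxes &
                             births$day >= focalDay - optionWindowDays &
                             births$day <= focalDay - 1L])
  length(occ) / length(regularBoxes)
}

#' Build the choice-event table of a colony
#'
#' Constructs, for every focal birth, the choice set: her home area over the
#' 30-day pre-birth window, the option females with their covariates (pup age
#' at focal birth, absolute observed litter-size difference, shared regular
#' boxes, absolute age difference, option age, pairwise relatedness from the
#' year-cohort Wang estimate, association seconds over the focal window,
#' whether the option litter was still solitary), the occupancy proportion P,
#' and the outcome: y = 1 when the focal joined an existing litter (the
#' mother of the youngest qualifying litter in her box is the chosen
#' partner). Cryptic same-day nests designate a focal at random (seeded); a
#' focal joining an existing cryptic nest receives one averaged pseudo-option
#' in place of the two residents. Births with no option are excluded from the
#' decision analysis and reported separately; events with an option lacking
#' genotypes are flagged incomplete.
#'
#' @param colony a [ColonyDataset].
#' @param estimator relatedness estimator function (default [wangR]).
#' @param seed seed for cryptic focal designation.
#' @return object of class `choiceTable`: list with `events` (one row per
#'   retained ChoiceEvent), `options` (one row per event x option),
#'   `excluded` (births without options or home area) and `litters` (the
#'   litter classification).
#' @export
buildChoiceTable <- function(colony, estimator = wangR, seed = 1L) {
  births <- colonyBirths(colony)
  ped <- colonyPedigree(colony)
  gt <- colonyGenotypes(colony)
  cfg <- colony@config
  optWin <- cfg$optionWindowDays %||% 16L
  trkWin <- cfg$trackingWindowDays %||% 30L
  dt <- eventsDT(colonyEvents(colony))
  cls <- classifyLitters(births, gapDays = optWin)
  pday <- setNames(ped$day, ped$id)
  psex <- setNames(ped$sex, ped$id)
  gids <- genotypeIds(gt)

  # seeded focal designation for founding cryptic pairs
  crypticFocal <- rep(TRUE, nrow(births))
  founding <- which(cls$cryptic & cls$joinOrder == 1L)
  if (length(founding)) {
    for (g in unique(cls$group[founding])) {
      members <- founding[cls$group[founding] == g]
      rc <- resolveCryptic(births$mother[members], seed = seed + g)
      crypticFocal[members] <- births$mother[members] == rc$focal
    }
  }

  haCache <- new.env(parent = emptyenv())
  getHA <- function(m, d) {
    key <- paste0(m, "@", d)
    got <- haCache[[key]]
    if (is.null(got)) {
      got <- homeAreaDT(dt, m, d, trkWin, 300)
      haCache[[key]] <- got
    }
    got
  }

  evRows <- list(); opRows <- list(); exRows <- list()
  for (i in seq_len(nrow(births))) {
    m <- births$mother[i]; d <- births$day[i]; bx <- births$box[i]
    if (cls$cryptic[i] && cls$joinOrder[i] == 1L && !crypticFocal[i]) {
      exRows[[length(exRows) + 1L]] <-
        data.frame(litter = i, mother = m, day = d, reason = "cryptic_resident")
      next
    }
    ha <- getHA(m, d)
    if (!length(ha$regularBoxes)) {
      exRows[[length(exRows) + 1L]] <-
        data.frame(litter = i, mother = m, day = d, reason = "no_home_area")
      next
    }
    op <- optionFemales(m, d, bx, ha$regularBoxes, births, optWin)
    if (cls$cryptic[i])  # the same-day partner(s) in her own box qualify
      op <- op[op$day < d | op$box == bx, ]
    if (!nrow(op)) {
      exRows[[length(exRows) + 1L]] <-
        data.frame(litter = i, mother = m, day = d, reason = "no_option")
      next
    }
    P <- occupancyProportion(m, d, ha$regularBoxes, births, optWin)

    # outcome: joined an existing qualifying litter in her own box?
    inBox <- which(op$box == bx & (op$day < d | cls$cryptic[i]))
    y <- as.integer(length(inBox) > 0L)
    chosenLitters <- integer(0)
    if (y == 1L) {
      young <- inBox[op$day[inBox] == max(op$day[inBox])]
      chosenLitters <- op$litter[young]
    }

    op$litterDiff <- abs(births$observedSize[i] - births$observedSize[op$litter])
    op$sharedBoxes <- vapply(seq_len(nrow(op)), function(k) {
      oha <- getHA(op$optionId[k], op$day[k])
      length(intersect(ha$regularBoxes, oha$regularBoxes))
    }, numeric(1))
    fday <- if (m %in% names(pday)) pday[[m]] else NA_integer_
    op$optionAge <- d - unname(pday[op$optionId])
    op$ageDiff <- abs(unname(pday[op$optionId]) - fday)
    op$assocS <- vapply(seq_len(nrow(op)), function(k)
      meetingsDT(dt, m, op$optionId[k], (d - trkWin) * DAY_S, d * DAY_S)$seconds,
      numeric(1))
    # option litter still solitary at the focal birth?
    op$optionSolitary <- vapply(op$litter, function(l) {
      peers <- cls$group == cls$group[l] & seq_len(nrow(births)) != l &
        births$day <= d - 1L
      sum(peers) == 0L
    }, logical(1))
    op$juvenileFamiliar <- juvenileFamiliarFlag(m, op$optionId, ped, cls, births)
    op$chosen <- op$litter %in% chosenLitters
    op$eventId <- i
    op$rhat <- NA_real_
    opRows[[length(opRows) + 1L]] <- op
    evRows[[length(evRows) + 1L]] <- data.frame(
      eventId = i, mother = m, day = d, box = bx,
      nRegular = length(ha$regularBoxes), nOptions = nrow(op), P = P, y = y,
      cryptic = cls$cryptic[i], stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, evRows)
  options <- do.call(rbind, opRows)
  excluded <- if (length(exRows)) do.call(rbind, exRows) else
    data.frame(litter = integer(), mother = character(), day = integer(),
               reason = character())

  # pairwise relatedness against the focal, year-cohort reference frequencies
  options$focal <- events$mother[match(options$eventId, events$eventId)]
  canGeno <- options$focal %in% gids & options$optionId %in% gids
  yr <- dayToYear(events$day[match(options$eventId, events$eventId)])
  for (y_ in unique(yr)) {
    rows <- which(canGeno & yr == y_)
    if (!length(rows)) next
    cohort <- cohortFemales(ped, gids, y_)
    fr <- alleleFrequencies(gt, cohort)
    est <- estimator(gt, data.frame(id1 = options$focal[rows],
                                    id2 = options$optionId[rows]), fr)
    options$rhat[rows] <- est$rhat
  }
  events$incomplete <- vapply(events$eventId, function(e)
    anyNA(options$rhat[options$eventId == e]), logical(1))

  # collapse the two residents of a joined cryptic nest into one averaged
  # pseudo-option (the chosen one, when the focal joined)
  options <- collapseCrypticResidents(events, options)
  events$chosenOption <- vapply(events$eventId, function(e) {
    ch <- options$optionId[options$eventId == e & options$chosen]
    if (length(ch)) ch[1] else NA_character_
  }, character(1))

  structure(list(events = events, options = options, excluded = excluded,
                 litters = cls),
            class = "choiceTable")
}

# Average the covariates of >1 chosen residents (a joined cryptic nest) into
# a single pseudo-option row.
collapseCrypticResidents <- function(events, options) {
  out <- list()
  for (e in unique(options$eventId)) {
    op <- options[options$eventId == e, ]
    ch <- which(op$chosen)
    if (length(ch) > 1L) {
      avg <- op[ch[1], ]
      avg$optionId <- paste0("cryptic:", paste(sort(op$optionId[ch]), collapse = "+"))
      num <- c("pupAge", "litterDiff", "sharedBoxes", "optionAge", "ageDiff",
               "assocS", "rhat")
      for (v in num) avg[[v]] <- mean(op[[v]][ch])
      avg$optionSolitary <- FALSE
      avg$juvenileFamiliar <- any(op$juvenileFamiliar[ch])
      op <- rbind(op[-ch, ], avg)
    }
    out[[length(out) + 1L]] <- op
  }
  do.call(rbind, out)
}

# Genotyped females forming the year cohort for reference allele frequencies:
# females whose adult life plausibly overlaps the year.
cohortFemales <- function(ped, gids, year) {
  fem <- ped$id[ped$sex == "F"]
  yrs <- dayToYear(ped$day[match(fem, ped$id)])
  cohort <- fem[yrs <= year & yrs >= year - 2L]
  cohort <- intersect(cohort, gids)
  if (length(cohort) < 10L) cohort <- intersect(ped$id[ped$sex == "F"], gids)
  cohort
}

# Descriptive juvenile-familiarity flag: focal and option born in the same
# litter, or their birth litters pooled in one communal nest group with an
# age gap <= 16 d.
juvenileFamiliarFlag <- function(focal, optionIds, ped, cls, births) {
  findBirthLitter <- function(id) {
    r <- match(id, ped$id)
    if (is.na(r) || is.na(ped$dam[r])) return(NA_integer_)
    hit <- which(births$mother == ped$dam[r] & births$day == ped$day[r])
    if (length(hit)) hit[1] else NA_integer_
  }
  fl <- findBirthLitter(focal)
  vapply(optionIds, function(o) {
    ol <- findBirthLitter(o)
    if (is.na(fl) || is.na(ol)) return(FALSE)
    cls$group[fl] == cls$group[ol]
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
print.choiceTable <- function(x, ...) {
  ev <- x$events
  cat(sprintf("choiceTable: %d choice events (%d communal, %d solitary), %d excluded births\n",
              nrow(ev), sum(ev$y), sum(ev$y == 0), nrow(x$excluded)))
  cat(sprintf("  options per event: mean %.2f (range %d-%d); %d incomplete events\n",
              mean(ev$nOptions), min(ev$nOptions), max(ev$nOptions),
              sum(ev$incomplete)))
  invisible(x)
}

#' Center and scale the continuous option covariates
#'
#' Z-scales the continuous explanatory variables of a choice table
#' (association time, pairwise relatedness, age difference, option age, pup
#' age, litter-size difference, shared boxes), storing the means and standard
#' deviations so the transformation is invertible.
#'
#' @param choices a `choiceTable` from [buildChoiceTable()].
#' @param vars covariates to scale.
#' @return the choice table with scaled `options` columns and a `scaling`
#'   element (data.frame var, center, scale).
#' @export
scaleCovariates <- function(choices,
                            vars = c("pupAge", "litterDiff", "sharedBoxes",
                                     "ageDiff", "optionAge", "rhat",
                                     "assocS")) {
  sc <- data.frame(var = vars, center = NA_real_, scale = NA_real_)
  for (k in seq_along(vars)) {
    v <- choices$options[[vars[k]]]
    mu <- mean(v, na.rm = TRUE); sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    sc$center[k] <- mu; sc$scale[k] <- sdv
    choices$options[[vars[k]]] <- (v - mu) / sdv
  }
  choices$scaling <- sc
  choices
}

#' Undo covariate scaling
#'
#' @param choices a scaled `choiceTable` (with a `scaling` element).
#' @return the choice table on the original covariate scale.
#' @export
unscaleCovariates <- function(choices) {
  sc <- choices$scaling
  if (is.null(sc)) return(choices)
  for (k in seq_len(nrow(sc))) {
    v <- choices$options[[sc$var[k]]]
    choices$options[[sc$var[k]]] <- v * sc$scale[k] + sc$center[k]
  }
  choices$scaling <- NULL
  choices
}
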