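#' Configuration for the synthetic colony generator
#'
#' Returns a validated configuration list for [simulateColony()]. Defaults
#' emulate the barn study design: a 72 m^2 barn in four sections of ten nest
#' boxes each, females using about five nest boxes regularly, kin-clustered
#' settlement of daughters near their mothers, 25 microsatellite loci with
#' eight alleles drawn from Dirichlet(1) founder frequencies, a 30-day
#' tracking window and a 16-day option window.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param nFounders founder individuals (half female).
#' @param nGenerations breeding generations after the founders.
#' @param nLoci,allelesPerLocus,dirichletConc microsatellite panel: loci,
#'   founder alleles per locus, Dirichlet concentration of founder
#'   frequencies.
#' @param barnSizeCm barn side lengths in cm.
#' @param nSections,boxesPerSection nest-box layout (sections impose no
#'   movement barrier).
#' @param dispersalMeanCm mean of the exponential mother-daughter home-center
#'   displacement (kin-clustering scale).
#' @param homeBoxesMean target mean number of regularly used nest boxes per
#'   female.
#' @param qualitySdLog log-sd of the lognormal nest-box quality weights.
#'   Boxes differ in attractiveness (position, shelter), so breeding activity
#'   concentrates in favoured boxes shared across females; 0 makes all boxes
#'   equal.
#' @param homeDecayCm distance decay scale of home-box choice: a female
#'   favours good boxes near her home center, so box sharing stays local and
#'   kin structure survives the quality concentration.
#' @param decisionMode `"random_box"`, `"power"` or `"preference"`.
#' @param powerA exponent used when `decisionMode = "power"`.
#' @param preferenceWeights list with `decision` (intercept and per-option
#'   slope of the communal-decision logit) and `partner` (conditional-logit
#'   weights on scaled option covariates: pup age / 16 d, association time /
#'   1800 s, pedigree relatedness).
#' @param optionWindowDays,trackingWindowDays option and tracking windows in
#'   days.
#' @param studyDays simulated horizon in days (two years).
#' @param littersPerFemale,maxBreedingFemales,litterMean,remateProb
#'   demography: litters per breeding female, cap on breeders per generation,
#'   Poisson mean litter size (truncated at 1), probability of switching sire
#'   between litters.
#' @param visitsPerDay,meanStayS movement intensity: nest-box visits per day
#'   and mean stay duration in seconds.
#' @param activeDays,matureAgeDays movement-tracking span per female and age
#'   at which females start moving/breeding eligibility.
#' @param missingRate per-genotype missing-data probability.
#' @param deathRate per-pup probability of dying before litter discovery
#'   (observed litter size = birth size minus such deaths).
#' @param detectProb probability a resident female is detected at a nest
#'   check.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nFounders = 32L,
                      nGenerations = 3L,
                      nLoci = 25L,
                      allelesPerLocus = 8L,
                      dirichletConc = 1,
                      barnSizeCm = c(850, 850),
                      nSections = 4L,
                      boxesPerSection = 10L,
                      dispersalMeanCm = 100,
                      homeBoxesMean = 5,
                      qualitySdLog = 3.0,
                      homeDecayCm = 60,
                      decisionMode = c("random_box", "power", "preference"),
                      powerA = 1,
                      preferenceWeights = list(
                        decision = c(intercept = -0.6, nOptions = 0.25),
                        partner = c(pupAge = -1.5, association = 1.0,
                                    relatedness = 0.8)),
                      optionWindowDays = 16L,
                      trackingWindowDays = 30L,
                      studyDays = 720L,
                      littersPerFemale = 3L,
                      maxBreedingFemales = 50L,
                      litterMean = 5,
                      remateProb = 0.5,
                      visitsPerDay = 5,
                      meanStayS = 1800,
                      activeDays = 500L,
                      matureAgeDays = 60L,
                      missingRate = 0.02,
                      deathRate = 0,
                      detectProb = 0.5) {
  decisionMode <- match.arg(decisionMode)
  stopifnot(nLoci >= 1, powerA > 0, nFounders >= 4, allelesPerLocus >= 2,
            missingRate >= 0, missingRate < 1, deathRate >= 0, deathRate < 1)
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

#' @export
print.simConfig <- function(x, ...) {
  cat(sprintf(paste0("simConfig: seed %d, %d founders, %d generations, ",
                     "%d loci x %d alleles, mode '%s'\n"),
              x$seed, x$nFounders, x$nGenerations, x$nLoci,
              x$allelesPerLocus, x$decisionMode))
  invisible(x)
}

#' Nest-box layout for a configured barn
#'
#' Boxes are arranged on a regular grid within each of the four sections
#' (two columns of five boxes per section), with neighbouring boxes roughly a
#' metre apart.
#'
#' @param config a [simConfig()].
#' @return data.frame(box, x, y, section) with coordinates in cm.
#' @export
makeLayout <- function(config = simConfig()) {
  sx <- config$barnSizeCm[1] / 2; sy <- config$barnSizeCm[2] / 2
  rows <- 5L
  cols <- max(1L, config$boxesPerSection %/% rows)
  out <- do.call(rbind, lapply(seq_len(config$nSections), function(s) {
    x0 <- ((s - 1L) %% 2L) * sx
    y0 <- ((s - 1L) %/% 2L) * sy
    g <- expand.grid(cx = seq_len(cols), ry = seq_len(rows))
    g <- g[seq_len(config$boxesPerSection), , drop = FALSE]
    data.frame(x = x0 + g$cx * sx / (cols + 1),
               y = y0 + (g$ry - 0.5) * sy / rows,
               section = s)
  }))
  out$box <- seq_len(nrow(out))
  out[, c("box", "x", "y", "section")]
}

#' Simulate a multi-generation barn pedigree
#'
#' Founders (half female) are born before the study proper; each generation's
#' breeding females (capped) produce several litters sired by eligible males,
#' switching sires between litters with probability `remateProb` so that
#' maternal and paternal half-siblings arise. Birth days span two year
#' cohorts and generations overlap. The returned pedigree is checked to
#' supply at least 50 dyads of each calibration class (full-sib,
#' parent-offspring, half-sib, unrelated); an explicit error names any
#' missing class.
#'
#' @param config a [simConfig()].
#' @return data.frame(id, dam, sire, day, sex, gen) of class `pedigree`-like
#'   layout used throughout the package.
#' @export
simulatePedigree <- function(config = simConfig()) {
  withSeed(deriveSeed(config$seed, "pedigree"), {
    nf <- config$nFounders
    ped <- data.frame(id = paste0("I", seq_len(nf)),
                      dam = NA_character_, sire = NA_character_,
                      day = as.integer(round(runif(nf, -120, 0))),
                      sex = rep(c("F", "M"), length.out = nf),
                      gen = 0L, stringsAsFactors = FALSE)
    nextId <- nf + 1L
    for (g in seq_len(config$nGenerations)) {
      mothers <- ped$id[ped$sex == "F" & ped$gen == g - 1L]
      if (length(mothers) > config$maxBreedingFemales)
        mothers <- sample(mothers, config$maxBreedingFemales)
      newRows <- vector("list", 0L)
      for (m in mothers) {
        mrow <- match(m, ped$id)
        bday <- ped$day[mrow] + round(runif(1, 150, 210))
        sire <- NA_character_
        for (litt in seq_len(config$littersPerFemale)) {
          if (litt > 1L) bday <- bday + round(runif(1, 45, 75))
          if (bday > config$studyDays - 15L) break
          if (is.na(sire) || runif(1) < config$remateProb) {
            conception <- bday - 20L
            males <- ped[ped$sex == "M" & ped$day <= conception - 100L, ]
            if (!nrow(males)) next
            # avoid matings with her own sire or full/half brothers when possible
            bad <- males$id == ped$sire[mrow] |
              (!is.na(males$dam) & !is.na(ped$dam[mrow]) & males$dam == ped$dam[mrow]) |
              (!is.na(males$sire) & !is.na(ped$sire[mrow]) & males$sire == ped$sire[mrow])
            pool <- males$id[!bad %in% TRUE]
            if (!length(pool)) pool <- males$id
            sire <- sample(pool, 1L)
          }
          size <- max(1L, rpois(1L, config$litterMean))
          kids <- data.frame(id = paste0("I", seq.int(nextId, nextId + size - 1L)),
                             dam = m, sire = sire, day = as.integer(bday),
                             sex = sample(c("F", "M"), size, replace = TRUE),
                             gen = g, stringsAsFactors = FALSE)
          nextId <- nextId + size
          newRows[[length(newRows) + 1L]] <- kids
        }
      }
      if (length(newRows)) ped <- rbind(ped, do.call(rbind, newRows))
    }
    for (cls in c("full-sib", "parent-offspring", "half-sib", "unrelated")) {
      got <- nrow(enumerateDyads(ped, cls, ids = NULL, contempDays = 365,
                                 target = 50L))
      if (got < 50L)
        stop(sprintf(paste0("pedigree config infeasible: only %d '%s' dyads ",
                            "available (need 50); increase founders/",
                            "generations"), got, cls))
    }
    ped
  })
}

#' Simulate multilocus microsatellite genotypes down a pedigree
#'
#' Founder allele frequencies are drawn per locus from a symmetric Dirichlet;
#' founders sample two alleles from them, and every non-founder receives one
#' allele Mendelian-sampled from each parent. An individual with one known
#' parent receives a Mendelian allele from that parent and a population
#' allele for the other gene. Genotypes are set missing with probability
#' `missingRate`.
#'
#' @param pedigree pedigree data.frame as from [simulatePedigree()].
#' @param config a [simConfig()].
#' @return a [genotypeTable] with the generating frequencies attached as
#'   `founderFreqs`.
#' @export
simulateGenotypes <- function(pedigree, config = simConfig()) {
  withSeed(deriveSeed(config$seed, "genotypes"), {
    n <- nrow(pedigree); L <- config$nLoci; k <- config$allelesPerLocus
    freqs <- lapply(seq_len(L), function(l) {
      p <- rgamma(k, config$dirichletConc)
      setNames(p / sum(p), as.character(seq_len(k)))
    })
    names(freqs) <- paste0("L", seq_len(L))
    a1 <- matrix(NA_integer_, n, L, dimnames = list(pedigree$id, names(freqs)))
    a2 <- a1
    dam <- match(pedigree$dam, pedigree$id)
    sire <- match(pedigree$sire, pedigree$id)
    # generation-ordered passes so parents are always filled first
    depth <- rep(0L, n)
    repeat {
      nd <- pmax(ifelse(is.na(dam), 0L, depth[dam] + 1L),
                 ifelse(is.na(sire), 0L, depth[sire] + 1L))
      if (all(nd == depth)) break
      depth <- nd
    }
    for (l in seq_len(L)) {
      p <- freqs[[l]]
      for (d in sort(unique(depth))) {
        rows <- which(depth == d)
        fromDam <- rep(NA_integer_, length(rows))
        fromSire <- fromDam
        hasD <- !is.na(dam[rows]); hasS <- !is.na(sire[rows])
        if (any(hasD)) {
          dr <- dam[rows][hasD]
          pick <- runif(sum(hasD)) < 0.5
          fromDam[hasD] <- ifelse(pick, a1[dr, l], a2[dr, l])
        }
        if (any(hasS)) {
          sr <- sire[rows][hasS]
          pick <- runif(sum(hasS)) < 0.5
          fromSire[hasS] <- ifelse(pick, a1[sr, l], a2[sr, l])
        }
        draw <- function(m) sample.int(length(p), m, replace = TRUE, prob = p)
        fromDam[is.na(fromDam)] <- draw(sum(is.na(fromDam)))
        fromSire[is.na(fromSire)] <- draw(sum(is.na(fromSire)))
        a1[rows, l] <- fromDam
        a2[rows, l] <- fromSire
      }
    }
    if (config$missingRate > 0) {
      miss <- matrix(runif(n * L) < config$missingRate, n, L)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }
    genotypeTable(a1, a2, founderFreqs = freqs)
  })
}

# Active movement window (days) of a female; NULL if she never matures in time.
activeWindow <- function(birthDay, config) {
  a0 <- birthDay + config$matureAgeDays
  a1 <- min(a0 + config$activeDays, config$studyDays)
  if (a1 <= a0) NULL else c(a0, a1)
}

#' Simulate settlement and nest-box movement
#'
#' Females settle at a home center: founder females uniformly in the barn,
#' daughters displaced from their mother's center by an exponential distance
#' (mean `dispersalMeanCm`, uniform direction, clipped to the barn), which
#' produces the kin-clustered spatial structure. Each female concentrates her
#' visits on a small set of nest boxes near her center (set size Poisson
#' around `homeBoxesMean`, clamped to 2-9), with a 6% exploration rate of
#' short visits elsewhere; stays alternate with gaps so that per-individual
#' stays never overlap. Monthly nest-check detections are emitted directly
#' (each active female is detected with probability `detectProb` in one of
#' her home boxes).
#'
#' @param pedigree pedigree data.frame.
#' @param config a [simConfig()].
#' @param layout optional precomputed [makeLayout()] result.
#' @return list with `layout`, `homes` (data.frame id, x, y, nHome and the
#'   per-female home boxes as attribute), `events` (tag, box, entry_s,
#'   exit_s) and `detections` (id, check, day, box).
#' @export
simulateSettlement <- function(pedigree, config = simConfig(), layout = NULL) {
  if (is.null(layout)) layout <- makeLayout(config)
  withSeed(deriveSeed(config$seed, "settlement"), {
    fem <- pedigree[pedigree$sex == "F", ]
    fem <- fem[order(fem$gen, fem$day), ]
    cx <- setNames(rep(NA_real_, nrow(fem)), fem$id)
    cy <- cx
    for (r in seq_len(nrow(fem))) {
      m <- fem$dam[r]
      if (is.na(m) || is.na(cx[m])) {
        cx[r] <- runif(1, 0, config$barnSizeCm[1])
        cy[r] <- runif(1, 0, config$barnSizeCm[2])
      } else {
        d <- rexp(1, 1 / config$dispersalMeanCm)
        th <- runif(1, 0, 2 * pi)
        cx[r] <- min(max(cx[m] + d * cos(th), 5), config$barnSizeCm[1] - 5)
        cy[r] <- min(max(cy[m] + d * sin(th), 5), config$barnSizeCm[2] - 5)
      }
    }
    nHome <- pmin(9L, pmax(2L, rpois(nrow(fem), config$homeBoxesMean)))
    # shared nest-box quality: favoured boxes attract many females, so home
    # areas (and hence breeding) concentrate and overlap
    quality <- rlnorm(nrow(layout), 0, config$qualitySdLog)
    homeBoxes <- vector("list", nrow(fem)); names(homeBoxes) <- fem$id
    homeW <- homeBoxes
    for (r in seq_len(nrow(fem))) {
      d2 <- (layout$x - cx[r])^2 + (layout$y - cy[r])^2
      w <- quality * exp(-sqrt(d2) / config$homeDecayCm)
      pickIdx <- sample.int(nrow(layout), nHome[r], prob = w)
      homeBoxes[[r]] <- layout$box[pickIdx]
      # within her home set a female spreads visits fairly evenly (all home
      # boxes are regularly used); flatten the selection weights
      wj <- w[pickIdx]^0.25
      homeW[[r]] <- wj / sum(wj)
    }
    evs <- vector("list", nrow(fem))
    dets <- vector("list", nrow(fem))
    checkDays <- seq(45L, config$studyDays - 15L, by = 30L)
    gapMean <- DAY_S / config$visitsPerDay - config$meanStayS
    for (r in seq_len(nrow(fem))) {
      aw <- activeWindow(fem$day[r], config)
      if (is.null(aw)) next
      ndays <- aw[2] - aw[1]
      nv <- ceiling(ndays * config$visitsPerDay * 1.2)
      gaps <- rexp(nv, 1 / gapMean)
      durs <- pmax(60, rgamma(nv, shape = 2, scale = config$meanStayS / 2))
      explore <- runif(nv) < 0.06
      durs[explore] <- runif(sum(explore), 30, 200)
      entry <- aw[1] * DAY_S + cumsum(gaps + durs) - durs
      keep <- (entry + durs) < aw[2] * DAY_S
      if (!any(keep)) next
      entry <- entry[keep]; durs <- durs[keep]; explore <- explore[keep]
      box <- integer(length(entry))
      nh <- length(homeBoxes[[r]])
      box[!explore] <- homeBoxes[[r]][sample.int(nh, sum(!explore),
                                                 replace = TRUE,
                                                 prob = homeW[[r]])]
      if (any(explore))
        box[explore] <- sample(layout$box, sum(explore), replace = TRUE)
      evs[[r]] <- data.frame(tag = fem$id[r], box = box,
                             entry_s = round(entry), exit_s = round(entry + durs))
      inChk <- which(checkDays >= aw[1] & checkDays < aw[2])
      if (length(inChk)) {
        seen <- inChk[runif(length(inChk)) < config$detectProb]
        if (length(seen))
          dets[[r]] <- data.frame(id = fem$id[r], check = seen,
                                  day = checkDays[seen],
                                  box = homeBoxes[[r]][sample.int(nh, length(seen),
                                                                  replace = TRUE,
                                                                  prob = homeW[[r]])])
      }
    }
    events <- data.table::rbindlist(evs[!vapply(evs, is.null, logical(1))])
    events <- events[order(tag, entry_s)]
    # rounding to integer seconds can create zero-length stays or make a stay
    # touch/overlap its successor; drop such rows
    events <- events[exit_s > entry_s]
    repeat {
      bad <- events[, .I[c(FALSE, entry_s[-1] < exit_s[-.N])], by = tag]$V1
      if (!length(bad)) break
      events <- events[-bad]
    }
    events <- as.data.frame(events)
    homes <- data.frame(id = fem$id, x = cx, y = cy, nHome = nHome,
                        row.names = NULL, stringsAsFactors = FALSE)
    attr(homes, "homeBoxes") <- homeBoxes
    attr(homes, "homeWeights") <- homeW
    detections <- as.data.frame(data.table::rbindlist(
      dets[!vapply(dets, is.null, logical(1))]))
    list(layout = layout, homes = homes, events = events,
         detections = detections, checkDays = checkDays)
  })
}

#' Simulate births and communal-nursing decisions
#'
#' Walks the scheduled litters in chronological order. For each birth the
#' mother's regular nest boxes are derived from her simulated event log over
#' the 30-day pre-birth window, the occupancy proportion P (regular boxes
#' holding a litter born in the preceding 16 days divided by all regular
#' boxes) is computed, and the nest box / outcome is generated under the
#' configured decision rule:
#' \describe{
#'   \item{random_box}{the focal picks uniformly among her regular boxes and
#'     the litter is communal iff the picked box already holds a young
#'     litter.}
#'   \item{power}{communal with probability P^a; an occupied (resp. empty)
#'     regular box is then picked uniformly.}
#'   \item{preference}{the communal decision follows a logit in the number of
#'     option females, and the partner is drawn by conditional logit on
#'     scaled option covariates (pup age / 16 d, association time / 1800 s,
#'     pedigree relatedness).}
#' }
#' The full ground truth (mode, P, options with the covariate values used,
#' chosen partner, outcome and any forced flag) is recorded.
#'
#' @param pedigree pedigree data.frame.
#' @param settlement result of [simulateSettlement()].
#' @param config a [simConfig()].
#' @return list with `births` (mother, day, box, litterSize, observedSize,
#'   discoveryAge), `decisions` (one row per birth with P, y, partner, flags)
#'   and `options` (one row per birth x option with the covariates used).
#' @export
simulateBirthsDecisions <- function(pedigree, settlement,
                                    config = simConfig()) {
  withSeed(deriveSeed(config$seed, "decisions"), {
    dt <- eventsDT(settlement$events)
    homes <- settlement$homes
    homeBoxes <- attr(homes, "homeBoxes")
    px <- pedigreeIndex(pedigree)
    kinCache <- new.env(parent = emptyenv())
    # litters scheduled in the pedigree: one per (dam, day)
    kids <- pedigree[!is.na(pedigree$dam), ]
    lit <- unique(kids[, c("dam", "day")])
    lit <- lit[order(lit$day, runif(nrow(lit))), ]
    sizes <- as.data.frame(table(paste(kids$dam, kids$day)))
    litSize <- setNames(sizes$Freq, sizes$Var1)
    w <- config$preferenceWeights
    n <- nrow(lit)
    births <- data.frame(mother = lit$dam, day = lit$day, box = NA_integer_,
                         litterSize = as.integer(litSize[paste(lit$dam, lit$day)]),
                         observedSize = NA_integer_,
                         discoveryAge = sample(1:12, n, replace = TRUE),
                         stringsAsFactors = FALSE)
    dec <- data.frame(eventId = seq_len(n), mother = lit$dam, day = lit$day,
                      nRegular = NA_integer_, P = NA_real_,
                      nOptions = NA_integer_, y = NA_integer_,
                      partner = NA_character_, box = NA_integer_,
                      flag = "", stringsAsFactors = FALSE)
    opts <- vector("list", n)
    prevBox <- integer(0); prevDay <- integer(0); prevMother <- character(0)
    for (i in seq_len(n)) {
      m <- lit$dam[i]; d <- lit$day[i]
      ha <- homeAreaDT(dt, m, d, config$trackingWindowDays, 300)
      reg <- ha$regularBoxes
      flag <- ""
      if (!length(reg)) { reg <- homeBoxes[[m]]; flag <- "no_home_area" }
      recent <- which(prevDay >= d - config$optionWindowDays & prevDay <= d - 1L)
      occBoxes <- unique(prevBox[recent[prevBox[recent] %in% reg]])
      P <- length(occBoxes) / length(reg)
      # option females: mothers of qualifying litters in the regular boxes
      oIdx <- recent[prevBox[recent] %in% reg & prevMother[recent] != m]
      nOpt <- length(oIdx)
      optDf <- NULL
      if (nOpt) {
        assoc <- vapply(oIdx, function(j)
          meetingsDT(dt, m, prevMother[j],
                     (d - config$trackingWindowDays) * DAY_S,
                     d * DAY_S)$seconds, numeric(1))
        rel <- vapply(oIdx, function(j)
          2 * kinshipRec(match(m, px$id), match(prevMother[j], px$id),
                         px, kinCache), numeric(1))
        optDf <- data.frame(eventId = i, optionId = prevMother[oIdx],
                            optionLitter = oIdx,
                            pupAge = d - prevDay[oIdx],
                            box = prevBox[oIdx],
                            assocS = assoc, pedigreeR = rel,
                            chosen = FALSE, stringsAsFactors = FALSE)
      }
      mode <- config$decisionMode
      y <- 0L; partner <- NA_character_; box <- NA_integer_
      if (mode == "random_box") {
        box <- if (length(reg) == 1L) reg else sample(reg, 1L)
        inBox <- if (nOpt) which(optDf$box == box) else integer(0)
        y <- as.integer(length(inBox) > 0L || box %in% occBoxes)
        if (length(inBox)) {
          pick <- inBox[which.min(optDf$pupAge[inBox])]
          partner <- optDf$optionId[pick]; optDf$chosen[pick] <- TRUE
        } else if (y == 1L) flag <- paste0(flag, ";own_prev_litter")
      } else if (mode == "power") {
        y <- rbinom(1L, 1L, P^config$powerA)
        if (y == 1L) {
          box <- if (length(occBoxes) == 1L) occBoxes else sample(occBoxes, 1L)
          inBox <- which(optDf$box == box)
          if (length(inBox)) {
            pick <- inBox[which.min(optDf$pupAge[inBox])]
            partner <- optDf$optionId[pick]; optDf$chosen[pick] <- TRUE
          }
        } else {
          free <- setdiff(reg, occBoxes)
          box <- if (length(free) == 1L) free else sample(free, 1L)
        }
      } else { # preference
        if (!nOpt) {
          flag <- paste0(flag, ";no_option")
          box <- {
            free <- setdiff(reg, occBoxes)
            if (!length(free)) free <- reg
            if (length(free) == 1L) free else sample(free, 1L)
          }
        } else {
          eta <- w$decision[["intercept"]] + w$decision[["nOptions"]] * nOpt
          y <- rbinom(1L, 1L, stats::plogis(eta))
          free <- setdiff(reg, optDf$box)
          if (y == 0L && !length(free)) { y <- 1L; flag <- paste0(flag, ";forced_communal") }
          if (y == 1L) {
            u <- w$partner[["pupAge"]] * (optDf$pupAge / 16) +
              w$partner[["association"]] * (optDf$assocS / 1800) +
              w$partner[["relatedness"]] * optDf$pedigreeR
            pr <- exp(u - max(u)); pr <- pr / sum(pr)
            pick <- sample.int(nOpt, 1L, prob = pr)
            partner <- optDf$optionId[pick]; optDf$chosen[pick] <- TRUE
            box <- optDf$box[pick]
            optDf$utility <- u
          } else {
            box <- if (length(free) == 1L) free else sample(free, 1L)
          }
        }
      }
      births$box[i] <- box
      deaths <- if (config$deathRate > 0)
        rbinom(1L, births$litterSize[i], config$deathRate) else 0L
      births$observedSize[i] <- births$litterSize[i] - deaths
      dec$nRegular[i] <- length(reg); dec$P[i] <- P
      dec$nOptions[i] <- nOpt; dec$y[i] <- y
      dec$partner[i] <- partner; dec$box[i] <- box
      dec$flag[i] <- sub("^;", "", flag)
      opts[[i]] <- optDf
      prevBox <- c(prevBox, box); prevDay <- c(prevDay, d)
      prevMother <- c(prevMother, m)
    }
    options <- data.table::rbindlist(opts[!vapply(opts, is.null, logical(1))],
                                     fill = TRUE)
    list(births = births, decisions = dec, options = as.data.frame(options))
  })
}

#' Simulate a complete synthetic barn colony
#'
#' Runs the four generator stages (pedigree, genotypes, settlement/movement,
#' births/decisions) under seeds derived from the master seed and assembles a
#' [ColonyDataset] with full ground truth. Output is byte-identical across
#' runs with the same configuration.
#'
#' @param config a [simConfig()].
#' @return a [ColonyDataset] whose `truth` holds the generating allele
#'   frequencies, home centers, decision records and option covariates.
#' @export
simulateColony <- function(config = simConfig()) {
  ped <- simulatePedigree(config)
  gt <- simulateGenotypes(ped, config)
  st <- simulateSettlement(ped, config)
  bd <- simulateBirthsDecisions(ped, st, config)
  ColonyDataset(events = st$events, births = bd$births, pedigree = ped,
                genotypes = gt, layout = st$layout,
                detections = st$detections,
                truth = list(homes = st$homes, decisions = bd$decisions,
                             options = bd$options,
                             founderFreqs = gt$founderFreqs,
                             checkDays = st$checkDays,
                             mode = config$decisionMode,
                             powerA = config$powerA,
                             preferenceWeights = config$preferenceWeights),
                config = unclass(config))
}

#' Simulate a panel of dyads of known pedigree class
#'
#' Builds a pedigree of independent family units (dam, two sires, two full
#' siblings and one maternal half sibling each), simulates multilocus
#' genotypes down it, and returns `nPerClass` dyads per class -- full-sib,
#' parent-offspring, half-sib and unrelated (contemporaneous members of
#' different families) -- together with cohort allele frequencies computed
#' from all simulated individuals. Used for estimator unbiasedness checks.
#'
#' @param nPerClass dyads per class.
#' @param nLoci,allelesPerLocus,dirichletConc genotype panel parameters.
#' @param seed integer seed.
#' @param missingRate per-genotype missing probability (default 0).
#' @return list with `pedigree`, `genotypes`, `freqs` and `dyads` (a named
#'   list of 2-column data.frames per class).
#' @export
simulateDyadPanel <- function(nPerClass = 500, nLoci = 25,
                              allelesPerLocus = 8, dirichletConc = 1,
                              seed = 1L, missingRate = 0) {
  nf <- nPerClass
  dam <- paste0("D", seq_len(nf)); s1 <- paste0("S", seq_len(nf))
  s2 <- paste0("T", seq_len(nf))
  o1 <- paste0("A", seq_len(nf)); o2 <- paste0("B", seq_len(nf))
  o3 <- paste0("C", seq_len(nf))
  ped <- rbind(
    data.frame(id = c(dam, s1, s2), dam = NA_character_, sire = NA_character_,
               day = 0L, sex = rep(c("F", "M", "M"), each = nf),
               stringsAsFactors = FALSE),
    data.frame(id = c(o1, o2, o3), dam = rep(dam, 3L),
               sire = c(s1, s1, s2), day = 400L,
               sex = "F", stringsAsFactors = FALSE))
  cfg <- simConfig(seed = seed, nLoci = nLoci,
                   allelesPerLocus = allelesPerLocus,
                   dirichletConc = dirichletConc, missingRate = missingRate)
  gt <- simulateGenotypes(ped, cfg)
  dyads <- list(
    `full-sib` = data.frame(id1 = o1, id2 = o2, stringsAsFactors = FALSE),
    `parent-offspring` = data.frame(id1 = ifelse(seq_len(nf) %% 2L == 0L, dam, s1),
                                    id2 = o1, stringsAsFactors = FALSE),
    `half-sib` = data.frame(id1 = o1, id2 = o3, stringsAsFactors = FALSE),
    unrelated = data.frame(id1 = o1, id2 = o2[c(seq_len(nf)[-1], 1L)],
                           stringsAsFactors = FALSE))
  list(pedigree = ped, genotypes = gt, freqs = alleleFrequencies(gt),
       dyads = dyads)
}
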