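# Shared fixtures; the expensive colonies are simulated once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  got <- .cache[[key]]
  if (is.null(got)) {
    got <- force(expr)
    .cache[[key]] <- got
  }
  got
}

defaultColony <- function() cached("defaultColony", simulateColony(simConfig(seed = 1)))

defaultChoices <- function() cached("defaultChoices",
                                    buildChoiceTable(defaultColony(), seed = 7))

kinColony <- function() cached("kinColony",
                               simulateColony(simConfig(seed = 4, dispersalMeanCm = 50)))

smallConfig <- function(seed = 3, ...) {
  simConfig(seed = seed, nFounders = 16, nGenerations = 2, studyDays = 420,
            maxBreedingFemales = 14, activeDays = 360, ...)
}

locatedFromColony <- function(col) {
  det <- colonyDetections(col)
  lay <- colonyLayout(col)
  data.frame(id = det$id, check = det$check,
             x = lay$x[match(det$box, lay$box)],
             y = lay$y[match(det$box, lay$box)])
}

# A tiny genotype table from a list of individual -> list of c(a, b) per locus.
toyGenotypes <- function(g) {
  ids <- names(g)
  L <- length(g[[1]])
  a1 <- do.call(rbind, lapply(g, function(x) vapply(x, `[`, numeric(1), 1L)))
  a2 <- do.call(rbind, lapply(g, function(x) vapply(x, `[`, numeric(1), 2L)))
  dimnames(a1) <- dimnames(a2) <- list(ids, paste0("L", seq_len(L)))
  genotypeTable(a1, a2)
}

toyFreqs <- function(freq, n = 50) {
  structure(list(freq = freq, n = setNames(rep(n, length(freq)), names(freq)),
                 ids = character(0)),
            class = "alleleFrequencies")
}

# Events giving `female` one daily stay of `hours` hours in each listed box,
# over days [from, to).
regularStays <- function(female, boxes, from, to, hours = 1) {
  days <- seq(from, to - 1L)
  do.call(rbind, lapply(seq_along(boxes), function(k) {
    start <- days * 86400 + (k - 1L) * 2 * 3600 * hours + 3600
    data.frame(tag = female, box = boxes[k], entry_s = start,
               exit_s = start + hours * 3600)
  }))
}

# Hand-built ten-birth fixture with known option sets, P values and
# exclusions: seven females with fixed home boxes, ten litters.
# Hand analysis (option window [d-16, d-1], same-day only in own box):
#   B1  F5 d40  box5  -> no option (first birth)            EXCLUDED
#   B2  F1 d50  box2  -> B1 in box5, not in {1,2}           EXCLUDED
#   B3  F2 d58  box3  -> options {F1 (age 8)};   P = 1/2; y = 0
#   B4  F3 d66  box4  -> options {F2 (8)};       P = 1/2; y = 0
#   B5  F4 d74  box4  -> options {F3 (8)};       P = 1/2; y = 1, chose F3
#   B6  F7 d82  box3  -> options {F3 (16), F4 (8)}; P = 1/3; y = 0
#   B7  F6 d90  box4  -> options {F4 (16)};      P = 1/2; y = 1, chose F4
#   B8  F5 d98  box6  -> B6/B7 not in {5,6}                 EXCLUDED
#   B9  F2 d98  box2  -> options {F7 (16)};      P = 1/2; y = 0
#   B10 F3 d106 box3  -> options {F6 (16)};      P = 1/2; y = 0
toyHomeBoxes <- list(F1 = c(1, 2), F2 = c(2, 3), F3 = c(3, 4), F4 = c(4, 1),
                     F5 = c(5, 6), F6 = c(2, 4), F7 = c(2, 3, 4))
toyBirths <- data.frame(
  mother = c("F5", "F1", "F2", "F3", "F4", "F7", "F6", "F5", "F2", "F3"),
  day    = c( 40,   50,   58,   66,   74,   82,   90,   98,   98,   106),
  box    = c( 5,    2,    3,    4,    4,    3,    4,    6,    2,    3),
  stringsAsFactors = FALSE)
toyColony <- function() {
  cached("toyColony", {
    events <- do.call(rbind, lapply(names(toyHomeBoxes), function(f)
      regularStays(f, toyHomeBoxes[[f]], from = 0, to = 200)))
    births <- toyBirths
    births$litterSize <- c(5, 4, 6, 5, 3, 4, 5, 6, 4, 5)
    births$observedSize <- births$litterSize
    births$discoveryAge <- 5L
    ped <- data.frame(id = paste0("F", 1:7), dam = NA_character_,
                      sire = NA_character_, day = -300L, sex = "F",
                      stringsAsFactors = FALSE)
    cfgG <- simConfig(seed = 77, nLoci = 5, missingRate = 0)
    gt <- simulateGenotypes(ped, cfgG)
    lay <- data.frame(box = 1:8, x = rep(c(100, 200, 300, 400), 2),
                      y = rep(c(100, 300), each = 4), section = 1L)
    ColonyDataset(events = events, births = births, pedigree = ped,
                  genotypes = gt, layout = lay,
                  config = list(optionWindowDays = 16L,
                                trackingWindowDays = 30L))
  })
}

# Cryptic fixture: same-day litters of F1 and F2 in box 1, joined by F3.
crypticColony <- function() {
  cached("crypticColony", {
    homeBoxes <- list(F1 = c(1, 2), F2 = c(1, 2), F3 = c(1, 2))
    events <- do.call(rbind, lapply(names(homeBoxes), function(f)
      regularStays(f, homeBoxes[[f]], from = 0, to = 100)))
    births <- data.frame(mother = c("F1", "F2", "F3"), day = c(50, 50, 55),
                         box = c(1, 1, 1), litterSize = c(5, 4, 6),
                         observedSize = c(5, 4, 6), discoveryAge = 3L,
                         stringsAsFactors = FALSE)
    ped <- data.frame(id = paste0("F", 1:3), dam = NA_character_,
                      sire = NA_character_, day = -300L, sex = "F",
                      stringsAsFactors = FALSE)
    gt <- simulateGenotypes(ped, simConfig(seed = 5, nLoci = 10,
                                           missingRate = 0))
    lay <- data.frame(box = 1:2, x = c(100, 200), y = 100, section = 1L)
    ColonyDataset(events = events, births = births, pedigree = ped,
                  genotypes = gt, layout = lay,
                  config = list(optionWindowDays = 16L,
                                trackingWindowDays = 30L))
  })
}

# Brute-force 1-second co-presence oracle for association time.
bruteAssociation <- function(events, a, b, lo, hi) {
  secs <- lo:(hi - 1L)
  occ <- function(id) {
    s <- events[events$tag == id, ]
    out <- rep(NA_integer_, length(secs))
    for (r in seq_len(nrow(s))) {
      cover <- secs >= s$entry_s[r] & secs < s$exit_s[r]
      out[cover] <- s$box[r]
    }
    out
  }
  oa <- occ(a); ob <- occ(b)
  sum(!is.na(oa) & !is.na(ob) & oa == ob)
}

# Gene-dropping oracle: average fraction of gene pairs shared IBD.
geneDrop <- function(ped, id1, id2, nDrop = 10000) {
  n <- nrow(ped)
  dam <- match(ped$dam, ped$id); sire <- match(ped$sire, ped$id)
  ord <- order(ped$day)
  i1 <- match(id1, ped$id); i2 <- match(id2, ped$id)
  tot <- 0
  g1 <- matrix(0L, n, 1); g2 <- g1
  for (d in seq_len(nDrop)) {
    a <- integer(n); b <- integer(n)
    nextGene <- 1L
    for (k in ord) {
      if (is.na(dam[k])) { a[k] <- nextGene; nextGene <- nextGene + 1L }
      else a[k] <- if (runif(1) < 0.5) a[dam[k]] else b[dam[k]]
      if (is.na(sire[k])) { b[k] <- nextGene; nextGene <- nextGene + 1L }
      else b[k] <- if (runif(1) < 0.5) a[sire[k]] else b[sire[k]]
    }
    sh <- (a[i1] == a[i2]) + (a[i1] == b[i2]) + (b[i1] == a[i2]) + (b[i1] == b[i2])
    tot <- tot + sh / 2
  }
  tot / nDrop
}
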