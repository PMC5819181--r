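#' Reference allele frequencies for a cohort
#'
#' Frequencies are obtained by straight allele counting over the chosen cohort
#' of individuals (the year cohort of the focal birth in the pipeline), with
#' per-locus sample sizes recorded. Monomorphic loci are retained with
#' frequency 1; the estimators skip them as uninformative.
#'
#' @param genotypes a [genotypeTable].
#' @param ids optional character vector restricting the cohort; default all.
#' @return list with `freq` (per locus, named numeric vector of allele
#'   frequencies), `n` (individuals typed per locus) and `ids`.
#' @export
alleleFrequencies <- function(genotypes, ids = NULL) {
  if (is.null(ids)) ids <- genotypeIds(genotypes)
  if (!length(ids)) stop("cohort is empty")
  idx <- match(ids, genotypeIds(genotypes))
  if (anyNA(idx)) stop("unknown individuals in cohort: ",
                       paste(head(ids[is.na(idx)]), collapse = ", "))
  a1 <- genotypes$a1[idx, , drop = FALSE]
  a2 <- genotypes$a2[idx, , drop = FALSE]
  L <- ncol(a1)
  freq <- vector("list", L); names(freq) <- colnames(a1)
  n <- integer(L); names(n) <- colnames(a1)
  for (l in seq_len(L)) {
    al <- c(a1[, l], a2[, l]); al <- al[!is.na(al)]
    n[l] <- length(al) %/% 2L
    if (!length(al)) { freq[[l]] <- numeric(0); next }
    tab <- table(al)
    freq[[l]] <- setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  structure(list(freq = freq, n = n, ids = ids), class = "alleleFrequencies")
}

#' @export
print.alleleFrequencies <- function(x, ...) {
  cat(sprintf("alleleFrequencies: %d loci, cohort of %d individuals\n",
              length(x$freq), length(x$ids)))
  invisible(x)
}

# Power sums of allele frequencies (a2, a3, a4) and the category-probability
# coefficients of the dyadic moment model at one locus:
#   b, d, f : P(category 1..3 | no pair of genes IBD)
#   c, e, g : the k1 - k0 contrasts of the same probabilities
# Categories: 1 identical genotypes; 2 homozygote vs heterozygote sharing one
# allele; 3 two heterozygotes sharing one allele; 4 no allele shared.
lociCoefficients <- function(freqs, biasCorrected = FALSE) {
  t(vapply(seq_along(freqs$freq), function(l) {
    p <- freqs$freq[[l]]
    if (biasCorrected && length(p)) {
      # unbiased estimators of sums of powers from the 2n sampled genes
      N <- unname(2 * freqs$n[l])
      cnt <- round(p * N)
      a2 <- sum(cnt * (cnt - 1)) / (N * (N - 1))
      a3 <- sum(cnt * (cnt - 1) * (cnt - 2)) / (N * (N - 1) * (N - 2))
      a4 <- sum(cnt * (cnt - 1) * (cnt - 2) * (cnt - 3)) /
        (N * (N - 1) * (N - 2) * (N - 3))
    } else {
      a2 <- sum(p^2); a3 <- sum(p^3); a4 <- sum(p^4)
    }
    c(a2 = a2, a3 = a3, a4 = a4,
      b = 2 * a2^2 - a4,
      c = a2 - 2 * a2^2 + a4,
      d = 4 * (a3 - a4),
      e = 2 * (a2 - 3 * a3 + 2 * a4),
      f = 4 * (a2 - a2^2 - 2 * a3 + 2 * a4),
      g = 1 - 7 * a2 + 4 * a2^2 + 10 * a3 - 8 * a4,
      u = 2 * a2 - a3)
  }, numeric(10)))
}

# Split a 2-column dyad spec (matrix or data.frame) into two character vectors.
dyadCols <- function(dyads) {
  if (is.data.frame(dyads)) list(as.character(dyads[[1]]), as.character(dyads[[2]]))
  else if (is.matrix(dyads)) list(as.character(dyads[, 1]), as.character(dyads[, 2]))
  else stop("dyads must be a 2-column matrix or data.frame of ids")
}

# Resolve a dyad specification into two index vectors in a genotype table.
resolveDyads <- function(genotypes, dyads) {
  ids <- genotypeIds(genotypes)
  dc <- dyadCols(dyads)
  i <- match(dc[[1]], ids)
  j <- match(dc[[2]], ids)
  if (anyNA(i) || anyNA(j)) stop("dyad member not present in genotype table")
  if (any(i == j)) stop("self-dyads are not defined")
  list(i = i, j = j)
}

# Per-dyad, per-locus genotype-sharing category (1..4), NA when either
# genotype is missing. Returns an m x L integer matrix.
dyadCategories <- function(genotypes, i, j) {
  A1 <- genotypes$a1[i, , drop = FALSE]; A2 <- genotypes$a2[i, , drop = FALSE]
  B1 <- genotypes$a1[j, , drop = FALSE]; B2 <- genotypes$a2[j, , drop = FALSE]
  ident <- A1 == B1 & A2 == B2
  hom1 <- A1 == A2; hom2 <- B1 == B2
  shared <- A1 == B1 | A1 == B2 | A2 == B1 | A2 == B2
  cat <- ifelse(ident, 1L,
         ifelse(shared & (hom1 | hom2), 2L,
         ifelse(shared, 3L, 4L)))
  cat[is.na(A1) | is.na(B1)] <- NA_integer_
  cat
}

#' Wang moment estimator of pairwise relatedness
#'
#' Moment estimator for codominant loci built from the four genotype-sharing
#' categories of a dyad at each locus. With reference allele frequencies the
#' expected category probabilities are linear in the two-gene (phi) and
#' four-gene (Delta) identity-by-descent coefficients; both are estimated
#' jointly by least squares on the three free category equations and combined
#' as r = phi/2 + Delta. Loci are pooled with weights 1/(2*a2 - a3), the
#' reference weighting that up-weights polymorphic loci; loci missing in either
#' member, or monomorphic, are skipped for that dyad.
#'
#' @param genotypes a [genotypeTable].
#' @param dyads two-column matrix or data.frame of individual ids.
#' @param freqs an [alleleFrequencies] object giving reference frequencies.
#' @return data.frame with columns `id1`, `id2`, `estimator`, `rhat`, `phi`,
#'   `delta`, `lociUsed`. `rhat` is `NA` (flagged via `lociUsed`) when fewer
#'   than 2 loci are usable.
#' @param biasCorrected use finite-sample unbiased estimators of the allele
#'   frequency power sums (a2, a3, a4) instead of the plug-in sums; the
#'   large-sample form is the default.
#' @param excludeDyad recompute the reference frequencies leaving the two
#'   dyad members out (slower; default FALSE keeps the full cohort including
#'   the dyad).
#' @export
wangR <- function(genotypes, dyads, freqs, biasCorrected = FALSE,
                  excludeDyad = FALSE) {
  if (excludeDyad) {
    dc <- dyadCols(dyads)
    out <- lapply(seq_along(dc[[1]]), function(k) {
      fr <- alleleFrequencies(genotypes, setdiff(freqs$ids, c(dc[[1]][k], dc[[2]][k])))
      wangR(genotypes, data.frame(id1 = dc[[1]][k], id2 = dc[[2]][k]), fr,
            biasCorrected = biasCorrected)
    })
    return(do.call(rbind, out))
  }
  rd <- resolveDyads(genotypes, dyads)
  cf <- lociCoefficients(freqs, biasCorrected = biasCorrected)
  cats <- dyadCategories(genotypes, rd$i, rd$j)
  informative <- cf[, "a2"] < 1 - 1e-9
  usable <- !is.na(cats) & rep(informative, each = nrow(cats))
  w <- matrix(rep(1 / cf[, "u"], each = nrow(cats)), nrow(cats))
  w[!usable] <- 0
  wsum <- rowSums(w)
  lociUsed <- rowSums(usable)
  wn <- w / ifelse(wsum > 0, wsum, 1)

  wavg <- function(col) as.vector(wn %*% cf[, col])
  P1 <- rowSums(wn * (cats == 1L), na.rm = TRUE)
  P2 <- rowSums(wn * (cats == 2L), na.rm = TRUE)
  P3 <- rowSums(wn * (cats == 3L), na.rm = TRUE)
  b <- wavg("b"); cc <- wavg("c"); d <- wavg("d")
  e <- wavg("e"); f <- wavg("f"); g <- wavg("g")

  # least-squares solve of (P1-b, P2-d, P3-f) = A (phi, Delta) with
  # A = [[c, 1-b], [e, -d], [g, -f]], per dyad
  y1 <- P1 - b; y2 <- P2 - d; y3 <- P3 - f
  M11 <- cc^2 + e^2 + g^2
  M12 <- cc * (1 - b) - e * d - g * f
  M22 <- (1 - b)^2 + d^2 + f^2
  v1 <- cc * y1 + e * y2 + g * y3
  v2 <- (1 - b) * y1 - d * y2 - f * y3
  det <- M11 * M22 - M12^2
  phi <- (M22 * v1 - M12 * v2) / det
  delta <- (M11 * v2 - M12 * v1) / det
  rhat <- phi / 2 + delta
  low <- lociUsed < 2L
  rhat[low] <- NA_real_; phi[low] <- NA_real_; delta[low] <- NA_real_
  data.frame(id1 = genotypeIds(genotypes)[rd$i],
             id2 = genotypeIds(genotypes)[rd$j],
             estimator = "wang", rhat = rhat, phi = phi, delta = delta,
             lociUsed = lociUsed, stringsAsFactors = FALSE)
}

#' Queller-Goodnight estimator of pairwise relatedness
#'
#' Ratio-of-sums moment estimator: for each direction the per-locus numerator
#' is the mean sharing of the focal's alleles minus their reference
#' frequencies, the denominator the focal's heterozygosity term; numerators
#' and denominators are summed across loci before taking the ratio, and the
#' two directions are averaged. Monomorphic or missing loci are skipped.
#'
#' @inheritParams wangR
#' @return data.frame with columns `id1`, `id2`, `estimator`, `rhat`,
#'   `lociUsed`.
#' @export
quellerGoodnightR <- function(genotypes, dyads, freqs) {
  rd <- resolveDyads(genotypes, dyads)
  cf <- lociCoefficients(freqs)
  informative <- cf[, "a2"] < 1 - 1e-9
  m <- length(rd$i); L <- ncol(genotypes$a1)
  lookup <- function(l, al) {
    p <- freqs$freq[[l]]
    out <- rep(NA_real_, length(al))
    ok <- !is.na(al)
    out[ok] <- p[as.character(al[ok])]
    out
  }
  numx <- numd <- numy <- denx <- deny <- rep(0, m)
  used <- rep(0L, m)
  for (l in seq_len(L)) {
    if (!informative[l]) next
    a <- genotypes$a1[rd$i, l]; b <- genotypes$a2[rd$i, l]
    c_ <- genotypes$a1[rd$j, l]; d_ <- genotypes$a2[rd$j, l]
    ok <- !is.na(a) & !is.na(c_)
    if (!any(ok)) next
    pa <- lookup(l, a); pb <- lookup(l, b)
    pc <- lookup(l, c_); pd_ <- lookup(l, d_)
    share <- 0.5 * ((a == c_) + (a == d_) + (b == c_) + (b == d_))
    nx <- share - pa - pb
    dx <- 1 + (a == b) - pa - pb
    ny <- share - pc - pd_
    dy <- 1 + (c_ == d_) - pc - pd_
    numx[ok] <- numx[ok] + nx[ok]; denx[ok] <- denx[ok] + dx[ok]
    numy[ok] <- numy[ok] + ny[ok]; deny[ok] <- deny[ok] + dy[ok]
    used[ok] <- used[ok] + 1L
  }
  rhat <- 0.5 * (numx / denx + numy / deny)
  rhat[used < 1L | denx == 0 | deny == 0] <- NA_real_
  data.frame(id1 = genotypeIds(genotypes)[rd$i],
             id2 = genotypeIds(genotypes)[rd$j],
             estimator = "qg", rhat = rhat, lociUsed = used,
             stringsAsFactors = FALSE)
}

# --- pedigree expected relatedness ------------------------------------------

# Build fast integer lookups from a pedigree data.frame.
pedigreeIndex <- function(pedigree) {
  id <- as.character(pedigree$id)
  list(id = id,
       dam = match(as.character(pedigree$dam), id),
       sire = match(as.character(pedigree$sire), id),
       day = pedigree$day)
}

# Kinship coefficient by the standard recursion (founders unrelated,
# unknown parents treated as founders). `i`, `j` are row indices; `px` the
# pedigreeIndex; `cache` an environment memoising pair values.
kinshipRec <- function(i, j, px, cache) {
  if (is.na(i) || is.na(j)) return(0)
  key <- if (i <= j) paste0(i, "|", j) else paste0(j, "|", i)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (i == j) {
    0.5 * (1 + kinshipRec(px$dam[i], px$sire[i], px, cache))
  } else {
    # recurse on the younger individual (parents are strictly older)
    if (px$day[i] < px$day[j]) { tmp <- i; i <- j; j <- tmp }
    0.5 * (kinshipRec(px$dam[i], j, px, cache) +
           kinshipRec(px$sire[i], j, px, cache))
  }
  cache[[key]] <- val
  val
}

# Ancestor ids up to the grandparental generation (self, parents,
# grandparents), as integer row indices.
grandparentSet <- function(i, px) {
  par <- c(px$dam[i], px$sire[i])
  gp <- c(px$dam[par], px$sire[par])
  unique(c(i, par[!is.na(par)], gp[!is.na(gp)]))
}

#' Pedigree expected relatedness and dyad class
#'
#' Computes the coefficient of relationship (twice the kinship coefficient
#' obtained by path counting over common ancestors, founders treated as
#' unrelated and non-inbred) and assigns a pedigree class: full siblings and
#' parent-offspring (expected r = 0.5), half siblings (r = 0.25), unrelated
#' (r = 0; contemporaneous and sharing no grandparent), or `other`.
#'
#' @param pedigree data.frame(id, dam, sire, day, sex).
#' @param dyads two-column matrix/data.frame of ids.
#' @param contempDays two individuals are contemporaneous when their birth
#'   days differ by at most this many days (default 365).
#' @return data.frame(id1, id2, expectedR, class).
#' @export
pedigreeExpectedR <- function(pedigree, dyads, contempDays = 365) {
  px <- pedigreeIndex(pedigree)
  dc <- dyadCols(dyads)
  i <- match(dc[[1]], px$id)
  j <- match(dc[[2]], px$id)
  if (anyNA(i) || anyNA(j)) stop("dyad member not present in pedigree")
  cache <- new.env(parent = emptyenv())
  r <- mapply(function(a, b) 2 * kinshipRec(a, b, px, cache), i, j)
  cls <- mapply(function(a, b) classifyDyadIdx(a, b, px, contempDays), i, j)
  data.frame(id1 = px$id[i], id2 = px$id[j], expectedR = r, class = cls,
             stringsAsFactors = FALSE)
}

classifyDyadIdx <- function(a, b, px, contempDays) {
  if (a == b) return("other")
  if (identical(px$dam[a], b) || identical(px$sire[a], b) ||
      identical(px$dam[b], a) || identical(px$sire[b], a)) return("parent-offspring")
  shared <- sum(!is.na(px$dam[a]) && !is.na(px$dam[b]) && px$dam[a] == px$dam[b],
                !is.na(px$sire[a]) && !is.na(px$sire[b]) && px$sire[a] == px$sire[b])
  if (shared == 2L) return("full-sib")
  if (shared == 1L) return("half-sib")
  if (abs(px$day[a] - px$day[b]) <= contempDays &&
      !length(intersect(grandparentSet(a, px), grandparentSet(b, px))))
    return("unrelated")
  "other"
}

expectedRByClass <- c(`full-sib` = 0.5, `parent-offspring` = 0.5,
                      `half-sib` = 0.25, unrelated = 0)

# --- dyad sampling and calibration ------------------------------------------

#' Sample pedigree dyads of a given class
#'
#' Enumerates full-sib, half-sib and parent-offspring dyads from parent
#' sharing, and finds unrelated dyads (contemporaneous, sharing no
#' grandparent) by seeded rejection sampling; then samples `n` dyads without
#' replacement.
#'
#' @inheritParams pedigreeExpectedR
#' @param class one of `"full-sib"`, `"parent-offspring"`, `"half-sib"`,
#'   `"unrelated"`.
#' @param n number of dyads required.
#' @param seed integer seed.
#' @param ids optional subset of individual ids eligible for dyads.
#' @return data.frame(id1, id2) of `n` dyads.
#' @export
samplePedigreeDyads <- function(pedigree, class, n, seed = NULL, ids = NULL,
                                contempDays = 365) {
  withSeed(seed, {
    pool <- enumerateDyads(pedigree, class, ids, contempDays,
                           target = max(n * 4L, 200L))
    if (nrow(pool) < n)
      stop(sprintf("pedigree supplies only %d %s dyads (need %d)",
                   nrow(pool), class, n))
    pool[sample.int(nrow(pool), n), , drop = FALSE]
  })
}

enumerateDyads <- function(pedigree, class, ids, contempDays, target) {
  px <- pedigreeIndex(pedigree)
  keep <- if (is.null(ids)) seq_along(px$id) else match(as.character(ids), px$id)
  keep <- keep[!is.na(keep)]
  inKeep <- logical(length(px$id)); inKeep[keep] <- TRUE
  res <- if (class == "parent-offspring") {
    kid <- which((!is.na(px$dam) | !is.na(px$sire)) & inKeep)
    par <- ifelse(!is.na(px$dam[kid]), px$dam[kid], px$sire[kid])
    both <- which(!is.na(px$dam[kid]) & !is.na(px$sire[kid]))
    # use dam for some, sire for others, to mix parent sexes
    par[both[seq_along(both) %% 2L == 0L]] <- px$sire[kid[both[seq_along(both) %% 2L == 0L]]]
    ok <- inKeep[par]
    cbind(kid[ok], par[ok])
  } else if (class %in% c("full-sib", "half-sib")) {
    kid <- which((!is.na(px$dam) & !is.na(px$sire)) & inKeep)
    if (!length(kid)) return(data.frame(id1 = character(), id2 = character()))
    fam <- split(kid, paste(px$dam[kid], px$sire[kid]))
    fs <- do.call(rbind, lapply(fam[lengths(fam) > 1L], function(k) t(combn(k, 2L))))
    if (class == "full-sib") fs else {
      bydam <- split(kid, px$dam[kid])
      allp <- do.call(rbind, lapply(bydam[lengths(bydam) > 1L],
                                    function(k) t(combn(k, 2L))))
      bysire <- split(kid, px$sire[kid])
      allp2 <- do.call(rbind, lapply(bysire[lengths(bysire) > 1L],
                                     function(k) t(combn(k, 2L))))
      allp <- unique(rbind(allp, allp2))
      if (is.null(allp)) return(data.frame(id1 = character(), id2 = character()))
      fskey <- if (is.null(fs)) character() else paste(fs[, 1], fs[, 2])
      hs <- allp[!(paste(allp[, 1], allp[, 2]) %in% fskey), , drop = FALSE]
      # exclude pairs sharing one parent but related again through the other
      # side at the grandparental level (keeps expected r at 0.25)
      okhs <- vapply(seq_len(nrow(hs)), function(r) {
        a <- hs[r, 1]; b <- hs[r, 2]
        shared <- sum(!is.na(px$dam[a]) && !is.na(px$dam[b]) && px$dam[a] == px$dam[b],
                      !is.na(px$sire[a]) && !is.na(px$sire[b]) && px$sire[a] == px$sire[b])
        shared == 1L
      }, logical(1))
      hs[okhs, , drop = FALSE]
    }
  } else if (class == "unrelated") {
    found <- matrix(integer(), 0, 2)
    tries <- 0L
    while (nrow(found) < target && tries < 60L) {
      tries <- tries + 1L
      a <- sample(keep, min(4L * target, 4000L), replace = TRUE)
      b <- sample(keep, length(a), replace = TRUE)
      ok <- a < b & abs(px$day[a] - px$day[b]) <= contempDays
      a <- a[ok]; b <- b[ok]
      if (!length(a)) next
      ur <- vapply(seq_along(a), function(r)
        !length(intersect(grandparentSet(a[r], px), grandparentSet(b[r], px))),
        logical(1))
      found <- unique(rbind(found, cbind(a[ur], b[ur])))
    }
    found
  } else stop("unknown dyad class: ", class)
  if (is.null(res) || !nrow(res))
    return(data.frame(id1 = character(), id2 = character()))
  data.frame(id1 = px$id[res[, 1]], id2 = px$id[res[, 2]],
             stringsAsFactors = FALSE)
}

#' Estimator-selection calibration against the pedigree
#'
#' The calibration procedure used to pick a relatedness estimator: sample (per
#' seeded draw, without replacement) 50 dyads from each pedigree class
#' (full-sib and parent-offspring, expected r = 0.5; half-sib, r = 0.25;
#' unrelated, r = 0), estimate pairwise relatedness for every dyad with each
#' candidate estimator, and report the Pearson correlation between expected
#' and estimated r per estimator, ranked. A constant estimator has undefined
#' correlation and is reported as `NA`.
#'
#' @inheritParams pedigreeExpectedR
#' @param genotypes a [genotypeTable] covering the pedigree individuals.
#' @param estimators named list of estimator functions with signature
#'   `(genotypes, dyads, freqs)` returning a data.frame with `rhat`; defaults
#'   to Wang and Queller-Goodnight. The interface is pluggable: any function
#'   with this signature can be supplied.
#' @param nPerClass dyads per class (default 50).
#' @param seed integer seed for the dyad draw.
#' @param freqs optional [alleleFrequencies]; default computed from all
#'   genotyped individuals.
#' @return object of class `calibrationReport`: data.frame(estimator,
#'   correlation, rank, n) with the per-dyad table in `attr(, "dyads")`.
#' @export
estimatorCalibration <- function(pedigree, genotypes,
                                 estimators = list(wang = wangR,
                                                   qg = quellerGoodnightR),
                                 nPerClass = 50, seed = NULL, freqs = NULL) {
  classes <- c("full-sib", "parent-offspring", "half-sib", "unrelated")
  gids <- genotypeIds(genotypes)
  dyads <- do.call(rbind, lapply(seq_along(classes), function(k) {
    d <- samplePedigreeDyads(pedigree, classes[k], nPerClass,
                             seed = if (is.null(seed)) NULL else seed + k,
                             ids = gids)
    d$class <- classes[k]
    d
  }))
  dyads$expectedR <- expectedRByClass[dyads$class]
  if (is.null(freqs)) freqs <- alleleFrequencies(genotypes)
  out <- data.frame(estimator = names(estimators),
                    correlation = NA_real_, n = nrow(dyads))
  for (k in seq_along(estimators)) {
    est <- estimators[[k]](genotypes, dyads[, c("id1", "id2")], freqs)
    dyads[[paste0("rhat_", names(estimators)[k])]] <- est$rhat
    ok <- !is.na(est$rhat)
    if (sum(ok) > 2 && sd(est$rhat[ok]) > 0 && sd(dyads$expectedR[ok]) > 0)
      out$correlation[k] <- cor(dyads$expectedR[ok], est$rhat[ok])
  }
  out <- out[order(-out$correlation, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "dyads") <- dyads
  class(out) <- c("calibrationReport", "data.frame")
  out
}

#' @export
print.calibrationReport <- function(x, ...) {
  cat("Relatedness estimator calibration (expected vs estimated r)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
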