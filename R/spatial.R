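#' Squared genetic distance between two multilocus genotypes
#'
#' Codominant squared distance summed over loci, using the per-locus pattern
#' values: identical genotypes 0; homozygote vs heterozygote sharing one
#' allele (AA-AB) 1; heterozygotes sharing one allele (AB-AC) 1; disjoint
#' heterozygotes (AB-CD) 2; homozygote vs disjoint heterozygote (AA-BC) 3;
#' disjoint homozygotes (AA-BB) 4. Loci missing in either genotype are
#' skipped.
#'
#' @param genotypes a [genotypeTable].
#' @param id1,id2 individual ids.
#' @return nonnegative squared distance.
#' @export
genotypeSqDistance <- function(genotypes, id1, id2) {
  i <- match(id1, genotypeIds(genotypes)); j <- match(id2, genotypeIds(genotypes))
  if (is.na(i) || is.na(j)) stop("unknown individual")
  sum(pairLocusSqDist(genotypes$a1[i, ], genotypes$a2[i, ],
                      genotypes$a1[j, ], genotypes$a2[j, ]), na.rm = TRUE)
}

# Vectorized per-locus squared distance for aligned allele vectors.
pairLocusSqDist <- function(A1, A2, B1, B2) {
  ident <- A1 == B1 & A2 == B2
  hom1 <- A1 == A2; hom2 <- B1 == B2
  shared <- A1 == B1 | A1 == B2 | A2 == B1 | A2 == B2
  d <- ifelse(ident, 0,
       ifelse(hom1 & hom2, 4,
       ifelse(hom1 | hom2, ifelse(shared, 1, 3),
       ifelse(shared, 1, 2))))
  d[is.na(A1) | is.na(B1)] <- NA_real_
  d
}

# Full pairwise squared-distance matrix for a set of individuals.
genotypeDistanceMatrix <- function(genotypes, ids) {
  idx <- match(ids, genotypeIds(genotypes))
  if (anyNA(idx)) stop("unknown individuals in distance matrix")
  n <- length(idx)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  pr <- which(upper.tri(D), arr.ind = TRUE)
  a1 <- genotypes$a1[idx, , drop = FALSE]; a2 <- genotypes$a2[idx, , drop = FALSE]
  tot <- numeric(nrow(pr))
  for (l in seq_len(ncol(a1))) {
    dl <- pairLocusSqDist(a1[pr[, 1], l], a2[pr[, 1], l],
                          a1[pr[, 2], l], a2[pr[, 2], l])
    tot <- tot + ifelse(is.na(dl), 0, dl)
  }
  D[upper.tri(D)] <- tot
  D + t(D)
}

#' Locate genotyped females at nest checks
#'
#' Assigns each female the coordinates of the nest box she occupied at the
#' instant of each retained nest check (the female inside the box at the
#' check timestamp, per the event log); females not detected at a check are
#' omitted for that check. Simulated colonies carry detections directly; this
#' builder serves real event logs and small fixtures.
#'
#' @param events event log.
#' @param layout nest-box layout (box, x, y).
#' @param checkTimes numeric vector of check instants in seconds.
#' @param females optional subset of tags.
#' @return data.frame(id, check, box, x, y).
#' @export
buildLocatedDataset <- function(events, layout, checkTimes, females = NULL) {
  dt <- data.table::as.data.table(events)
  if (!is.null(females)) dt <- dt[tag %in% females]
  out <- lapply(seq_along(checkTimes), function(k) {
    t0 <- checkTimes[k]
    s <- dt[entry_s <= t0 & exit_s > t0]
    if (!nrow(s)) return(NULL)
    stopifnot(!anyDuplicated(s$tag))  # one box per individual per instant
    data.frame(id = s$tag, check = k, box = s$box)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(data.frame(id = character(), check = integer(),
                                      box = integer(), x = numeric(),
                                      y = numeric()))
  out$x <- layout$x[match(out$box, layout$box)]
  out$y <- layout$y[match(out$box, layout$box)]
  out
}

#' Spatial genetic autocorrelation correlogram
#'
#' For each nest check, a squared genetic distance matrix over the located
#' females is double-centered into a covariance matrix; the autocorrelation
#' coefficient of a geographic distance class is the ratio of the summed
#' between-individual centered covariances of in-class dyads to the
#' corresponding diagonal terms, with numerators and denominators pooled
#' across checks. Dyads are only formed within a check. Distance classes are
#' the singleton \{0\} (same box) followed by half-open rings
#' `(0, w], (w, 2w], ...`. The permutation null shuffles genotypes among the
#' located records within each check; the bootstrap CI resamples in-class
#' dyads. One-tailed permutation p (positive structure).
#'
#' @param located data.frame(id, check, x, y) as from
#'   [buildLocatedDataset()] or simulator detections joined to the layout.
#' @param genotypes a [genotypeTable].
#' @param classWidthCm ring width in cm (default 100).
#' @param nPerm permutations for the null band (default 999).
#' @param nBoot bootstrap resamples for the CI (default 1000).
#' @param seed integer seed.
#' @param maxDistCm largest ring edge; default covers the data.
#' @return data.frame of class `correlogram`: one row per distance class with
#'   `r`, `nDyads`, `nullLo`, `nullHi`, `bootLo`, `bootHi`, `p`.
#' @export
correlogram <- function(located, genotypes, classWidthCm = 100,
                        nPerm = 999, nBoot = 1000, seed = 1L,
                        maxDistCm = NULL) {
  checks <- split(located, located$check)
  checks <- checks[vapply(checks, nrow, integer(1)) >= 2L]
  if (!length(checks)) stop("need at least one nest check with >= 2 located genotypes")
  maxD <- max(vapply(checks, function(ck)
    max(dist(cbind(ck$x, ck$y))), numeric(1)))
  if (is.null(maxDistCm)) maxDistCm <- maxD
  nClass <- 1L + ceiling(maxDistCm / classWidthCm)
  classOf <- function(d) ifelse(d < 1e-9, 1L, 1L + pmin(ceiling(d / classWidthCm),
                                                        nClass - 1L))
  # per-check centered covariance and per-pair bookkeeping
  pairNum <- vector("list", length(checks))
  pairDen <- vector("list", length(checks))
  pairCls <- vector("list", length(checks))
  permdat <- vector("list", length(checks))
  for (k in seq_along(checks)) {
    ck <- checks[[k]]
    n <- nrow(ck)
    D <- genotypeDistanceMatrix(genotypes, ck$id)
    rm_ <- rowMeans(D); gm <- mean(D)
    C <- -0.5 * (D - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
    geo <- as.matrix(dist(cbind(ck$x, ck$y)))
    pr <- which(upper.tri(geo), arr.ind = TRUE)
    cls <- classOf(geo[upper.tri(geo)])
    pairNum[[k]] <- C[pr]
    pairDen[[k]] <- 0.5 * (diag(C)[pr[, 1]] + diag(C)[pr[, 2]])
    pairCls[[k]] <- cls
    permdat[[k]] <- list(C = C, pr = pr, cls = cls, n = n)
  }
  allNum <- unlist(pairNum); allDen <- unlist(pairDen); allCls <- unlist(pairCls)
  sumBy <- function(v, cls) {
    out <- numeric(nClass)
    s <- rowsum(v, cls)
    out[as.integer(rownames(s))] <- s
    out
  }
  num <- sumBy(allNum, allCls); den <- sumBy(allDen, allCls)
  nDy <- sumBy(rep(1, length(allCls)), allCls)
  r <- ifelse(nDy > 0 & den != 0, num / den, NA_real_)

  withSeed(seed, {
    permR <- matrix(NA_real_, nPerm, nClass)
    npair <- vapply(permdat, function(d) nrow(d$pr), integer(1))
    off <- cumsum(c(0L, npair))
    valN <- numeric(sum(npair)); valD <- valN
    diags <- lapply(permdat, function(d) diag(d$C))
    for (b in seq_len(nPerm)) {
      for (k in seq_along(permdat)) {
        pdk <- permdat[[k]]
        perm <- sample.int(pdk$n)
        i <- perm[pdk$pr[, 1]]; j <- perm[pdk$pr[, 2]]
        sl <- (off[k] + 1L):off[k + 1L]
        valN[sl] <- pdk$C[(j - 1L) * pdk$n + i]
        valD[sl] <- 0.5 * (diags[[k]][i] + diags[[k]][j])
      }
      pn <- sumBy(valN, allCls); pd <- sumBy(valD, allCls)
      permR[b, ] <- ifelse(nDy > 0 & pd != 0, pn / pd, NA_real_)
    }
    permMean <- colMeans(permR, na.rm = TRUE)
    nullLo <- apply(permR, 2, quantile, probs = 0.025, na.rm = TRUE)
    nullHi <- apply(permR, 2, quantile, probs = 0.975, na.rm = TRUE)
    p <- vapply(seq_len(nClass), function(cl) {
      if (nDy[cl] == 0 || is.na(r[cl])) return(NA_real_)
      (1 + sum(permR[, cl] >= r[cl], na.rm = TRUE)) / (nPerm + 1)
    }, numeric(1))

    bootLo <- bootHi <- rep(NA_real_, nClass)
    for (cl in seq_len(nClass)) {
      idx <- which(allCls == cl)
      if (length(idx) < 2L) next
      bs <- vapply(seq_len(nBoot), function(b) {
        take <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
        dn <- sum(allDen[take])
        if (dn == 0) NA_real_ else sum(allNum[take]) / dn
      }, numeric(1))
      bootLo[cl] <- quantile(bs, 0.025, na.rm = TRUE)
      bootHi[cl] <- quantile(bs, 0.975, na.rm = TRUE)
    }
    out <- data.frame(
      class = seq_len(nClass),
      lowerCm = c(0, 0, classWidthCm * seq_len(nClass - 2L)),
      upperCm = c(0, classWidthCm * seq_len(nClass - 1L)),
      r = r, nDyads = as.integer(nDy),
      permMean = permMean, nullLo = nullLo, nullHi = nullHi,
      bootLo = bootLo, bootHi = bootHi, p = p)
    class(out) <- c("correlogram", "data.frame")
    out
  })
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Spatial genetic autocorrelation correlogram\n")
  print.data.frame(format(x, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Plot a correlogram
#'
#' Autocorrelation r per distance class with the permutation null band and
#' bootstrap CIs.
#'
#' @param x a `correlogram`.
#' @param ... passed to [plot()].
#' @export
plotCorrelogram <- function(x, ...) {
  ok <- x$nDyads > 0 & !is.na(x$r)
  mid <- ifelse(x$upperCm == 0, 0, (x$lowerCm + x$upperCm) / 2)
  graphics::plot(mid[ok], x$r[ok], type = "b", pch = 16,
                 xlab = "distance class midpoint (cm)",
                 ylab = "autocorrelation r", ...)
  graphics::polygon(c(mid[ok], rev(mid[ok])),
                    c(x$nullLo[ok], rev(x$nullHi[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  graphics::arrows(mid[ok], x$bootLo[ok], mid[ok], x$bootHi[ok],
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
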