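#' Nest-availability power model y ~ P^a
#'
#' Fits the probability of communal nesting as a power function of the
#' occupancy proportion P by nonlinear least squares: a-hat minimises
#' sum (y_i - P_i^a)^2 over a > 0, starting at the random-choice null a = 1.
#' The curve passes through (0,0) and (1,1) for every a > 0, so a = 1 is the
#' natural null (communal nesting a pure by-product of nest availability);
#' a > 1 means communal nursing rarer than random expectation. The standard
#' error comes from the linearised Jacobian (d/da P^a = P^a log P, the P = 1
#' contribution being 0), and the two-sided test of a = 1 uses a t statistic
#' with n - 1 degrees of freedom. Events with P = 0 carry no information
#' about a and are excluded by default.
#'
#' @param P occupancy proportions in [0, 1].
#' @param y binary outcomes (1 communal, 0 solitary).
#' @param includeZeroP keep P = 0 events in the fit (default FALSE).
#' @param tol convergence tolerance on a (default 1e-8).
#' @return object of class `powerFit` with elements `a`, `se`, `t`, `df`,
#'   `p`, `n`, `rss`, `sigma2`, `converged`.
#' @export
fitPowerNull <- function(P, y, includeZeroP = FALSE, tol = 1e-8) {
  stopifnot(length(P) == length(y), all(P >= 0 & P <= 1, na.rm = TRUE),
            all(y %in% c(0, 1)))
  ok <- !is.na(P) & !is.na(y)
  if (!includeZeroP) ok <- ok & P > 0
  P <- P[ok]; y <- y[ok]
  n <- length(P)
  if (n < 3L) stop("too few events with P > 0 to fit the power model")
  if (all(P == 1)) stop("all P = 1: exponent a is unidentifiable")
  lp <- log(P)
  lp[P == 0] <- 0  # limit contribution of P = 0 terms is 0 for a > 0
  obj <- function(a) {
    f <- ifelse(P == 0, 0, P^a)
    sum((y - f)^2)
  }
  a <- 1
  converged <- FALSE
  for (it in seq_len(100L)) {
    f <- ifelse(P == 0, 0, P^a)
    res <- y - f
    g1 <- f * lp              # df/da
    grad <- -2 * sum(res * g1)
    hess <- 2 * sum(g1^2 - res * f * lp^2)
    step <- if (is.finite(hess) && hess > 0) -grad / hess else -sign(grad) * 0.1
    # damped step, keeping a > 0
    s0 <- obj(a)
    lambda <- 1
    repeat {
      anew <- a + lambda * step
      if (anew > 0 && obj(anew) <= s0 + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { anew <- a; break }
    }
    if (abs(anew - a) < tol) { a <- anew; converged <- TRUE; break }
    a <- anew
  }
  if (!converged) {
    o <- optimize(obj, c(1e-6, 50))
    if (o$objective <= obj(a)) a <- o$minimum
    converged <- TRUE
  }
  f <- ifelse(P == 0, 0, P^a)
  rss <- sum((y - f)^2)
  df <- n - 1L
  sigma2 <- rss / df
  jac2 <- sum((f * lp)^2)
  if (jac2 <= 0) stop("degenerate design: no curvature information for a")
  se <- sqrt(sigma2 / jac2)
  tstat <- (a - 1) / se
  pval <- 2 * pt(-abs(tstat), df)
  structure(list(a = a, se = se, t = tstat, df = df, p = pval, n = n,
                 rss = rss, sigma2 = sigma2, converged = converged),
            class = "powerFit")
}

#' @export
print.powerFit <- function(x, ...) {
  cat(sprintf("Nest-availability power model y ~ P^a (NLS, n = %d)\n", x$n))
  cat(sprintf("  a = %.3f (SE %.3f); H0 a = 1: t = %.2f, df = %d, p = %.4g\n",
              x$a, x$se, x$t, x$df, x$p))
  invisible(x)
}

#' Plot the fitted nest-availability power curve
#'
#' @param fit a `powerFit`.
#' @param P,y the data used for the fit (optional, plotted as rug marks).
#' @param ... passed to [graphics::curve()].
#' @export
plotPowerFit <- function(fit, P = NULL, y = NULL, ...) {
  a <- fit$a
  graphics::curve(x^a, 0, 1, xlab = "occupancy proportion P",
                  ylab = "probability of communal nest", col = "red", ...)
  graphics::abline(0, 1, lty = 2)
  if (!is.null(P)) graphics::rug(P, side = 1)
  if (!is.null(P) && !is.null(y)) graphics::rug(P[y == 1], side = 3)
  invisible(fit)
}

#' Binary logistic model of the decision to nurse communally
#'
#' Logistic regression (maximum likelihood via [glm()]) of the communal (1)
#' vs solitary (0) outcome on event-level predictors, the continuous ones
#' z-scaled first (stored means/SDs). Random effects are not fitted; the
#' coefficients are comparable in sign and direction to the mixed-model
#' analysis they stand in for. Constant covariates are dropped with a flag,
#' and coefficients beyond +-15 on the scaled scale are flagged as likely
#' separation.
#'
#' @param data data.frame of events.
#' @param response name of the binary response column (default "y").
#' @param predictors character vector of predictor columns.
#' @param scale z-scale continuous predictors (default TRUE).
#' @return object of class `choiceFit` with `coef` table, `logLik`, `n`,
#'   `scaling`, `dropped`, `flags` and the underlying `glm` fit.
#' @export
fitDecisionModel <- function(data, response = "y",
                             predictors = c("nOptions", "nRegular"),
                             scale = TRUE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  d <- data[, c(response, predictors)]
  d <- d[complete.cases(d), ]
  dropped <- character(0)
  scaling <- NULL
  for (v in predictors) {
    if (!is.numeric(d[[v]])) next
    sdv <- sd(d[[v]])
    if (sdv == 0) { dropped <- c(dropped, v); next }
    if (scale && length(unique(d[[v]])) > 2L) {
      scaling <- rbind(scaling, data.frame(var = v, center = mean(d[[v]]),
                                           scale = sdv))
      d[[v]] <- (d[[v]] - mean(d[[v]])) / sdv
    }
  }
  predictors <- setdiff(predictors, dropped)
  if (!length(predictors)) stop("no usable predictors (all constant)")
  fml <- stats::as.formula(paste(response, "~", paste(predictors, collapse = "+")))
  fit <- glm(fml, data = d, family = binomial())
  cf <- summary(fit)$coefficients
  flags <- character(0)
  if (any(abs(cf[, 1]) > 15)) flags <- c(flags, "possible separation")
  if (length(dropped)) flags <- c(flags, paste("constant predictor dropped:",
                                               paste(dropped, collapse = ", ")))
  structure(list(kind = "binary-decision logistic",
                 coef = data.frame(term = rownames(cf), estimate = cf[, 1],
                                   se = cf[, 2], z = cf[, 3], p = cf[, 4],
                                   row.names = NULL),
                 logLik = as.numeric(logLik(fit)), n = nrow(d),
                 scaling = scaling, dropped = dropped, flags = flags,
                 glm = fit),
            class = "choiceFit")
}

#' Conditional-logit model of communal-nursing partner choice
#'
#' Discrete-choice likelihood in which each communal event's chosen option
#' female competes only against that event's option set: the probability of
#' choosing option j is exp(x_j beta) / sum_k exp(x_k beta). Fitted by
#' Newton-Raphson on the conditional log-likelihood; single-option events
#' carry no contrast and contribute zero information (they are retained).
#' Events whose chosen option has missing covariates are dropped with a log
#' entry.
#'
#' @param options data.frame with one row per event x option, containing an
#'   event id column, a logical/0-1 `chosen` column and the covariates.
#' @param covariates character vector of covariate columns.
#' @param eventCol name of the event id column (default "eventId").
#' @param center center covariates within event before fitting (optional;
#'   the conditional likelihood is invariant to within-event location
#'   shifts).
#' @param tol Newton convergence tolerance on the gradient.
#' @return object of class `choiceFit` with `coef` table, `logLik`, `n`
#'   (events used), `probs` (fitted per-option probabilities) and `droppedEvents`.
#' @export
fitPartnerModel <- function(options, covariates, eventCol = "eventId",
                            center = FALSE, tol = 1e-8) {
  stopifnot(all(c(eventCol, "chosen", covariates) %in% names(options)))
  op <- options
  op$chosen <- as.logical(op$chosen)
  keepEv <- vapply(split(op, op[[eventCol]]), function(d) {
    sum(d$chosen) == 1L && !anyNA(d[d$chosen, covariates])
  }, logical(1))
  droppedEvents <- names(keepEv)[!keepEv]
  op <- op[op[[eventCol]] %in% names(keepEv)[keepEv], ]
  # options with missing covariates cannot be compared; drop the rows
  op <- op[complete.cases(op[, covariates, drop = FALSE]) | op$chosen, ]
  ev <- factor(op[[eventCol]])
  X <- as.matrix(op[, covariates, drop = FALSE])
  if (center) X <- X - rowsum(X, ev)[ev, , drop = FALSE] / as.vector(table(ev))[ev]
  chosen <- op$chosen
  k <- ncol(X)
  beta <- rep(0, k)
  evIdx <- split(seq_along(ev), ev)
  ll <- function(beta) {
    eta <- as.vector(X %*% beta)
    sum(vapply(evIdx, function(ii) {
      m <- max(eta[ii])
      eta[ii][chosen[ii]] - m - log(sum(exp(eta[ii] - m)))
    }, numeric(1)))
  }
  llPrev <- ll(beta)
  for (it in seq_len(100L)) {
    eta <- as.vector(X %*% beta)
    grad <- rep(0, k); H <- matrix(0, k, k)
    for (ii in evIdx) {
      m <- max(eta[ii])
      w <- exp(eta[ii] - m); w <- w / sum(w)
      xb <- colSums(X[ii, , drop = FALSE] * w)
      grad <- grad + X[ii, , drop = FALSE][chosen[ii], ] - xb
      Ew <- crossprod(X[ii, , drop = FALSE] * sqrt(w))
      H <- H + Ew - tcrossprod(xb)
    }
    if (max(abs(grad)) < tol) break
    step <- tryCatch(solve(H, grad), error = function(e) grad / (max(abs(H)) + 1))
    lambda <- 1
    repeat {
      bnew <- beta + lambda * step
      if (ll(bnew) >= llPrev - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { bnew <- beta; break }
    }
    beta <- bnew
    llPrev <- ll(beta)
  }
  eta <- as.vector(X %*% beta)
  probs <- unlist(lapply(evIdx, function(ii) {
    w <- exp(eta[ii] - max(eta[ii])); w / sum(w)
  }))[order(unlist(evIdx))]
  H <- matrix(0, k, k)
  for (ii in evIdx) {
    w <- exp(eta[ii] - max(eta[ii])); w <- w / sum(w)
    xb <- colSums(X[ii, , drop = FALSE] * w)
    H <- H + crossprod(X[ii, , drop = FALSE] * sqrt(w)) - tcrossprod(xb)
  }
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  se <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  se[se == 0] <- NA_real_
  z <- beta / se
  structure(list(kind = "conditional logit",
                 coef = data.frame(term = covariates, estimate = beta, se = se,
                                   z = z, p = 2 * pnorm(-abs(z)),
                                   row.names = NULL),
                 logLik = llPrev, n = length(evIdx), probs = probs,
                 droppedEvents = droppedEvents),
            class = "choiceFit")
}

#' @export
print.choiceFit <- function(x, ...) {
  cat(sprintf("%s (n = %d, logLik = %.2f)\n", x$kind, x$n, x$logLik))
  print(x$coef, row.names = FALSE, digits = 3)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank sum test
#'
#' Rank-sum test with midranks for ties. The statistic W is the number of
#' (a, b) pairs with a > b plus half the ties (the Mann-Whitney U of the
#' first sample). The two-sided p is exact (by complete enumeration of
#' arrangements) when the arrangement count is modest or min(n, m) <= 8,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric samples.
#' @param exactLimit largest number of arrangements enumerated exactly.
#' @return list with `W`, `p`, `method`.
#' @export
mannWhitney <- function(a, b, exactLimit = 5e5) {
  if (!length(a) || !length(b)) stop("empty sample")
  n <- length(a); m <- length(b)
  W <- uStat(a, b)
  useExact <- min(n, m) <= 8 && choose(n + m, n) <= exactLimit
  if (useExact) {
    pool <- c(a, b)
    idx <- combn(n + m, n)
    us <- vapply(seq_len(ncol(idx)), function(k)
      uStat(pool[idx[, k]], pool[-idx[, k]]), numeric(1))
    mu <- n * m / 2
    pLo <- mean(us <= W); pHi <- mean(us >= W)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(W = W, p = p, method = "exact enumeration"))
  }
  r <- rank(c(a, b))
  ties <- table(r)
  mu <- n * m / 2
  sg2 <- n * m / 12 * ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sqrt(sg2)
  list(W = W, p = min(1, 2 * pnorm(-abs(z))),
       method = "normal approximation with tie correction")
}

uStat <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Event-level permutation test of a scenario difference in means
#'
#' Tests whether option-level values (e.g. pairwise relatedness of all option
#' females) differ between the communal and the solitary scenario. The
#' observed statistic is the difference of means (first group minus second);
#' the null distribution permutes the scenario labels at the event level, so
#' all options of one event move together, respecting the nesting that the
#' original mixed-model analysis addressed with random effects.
#'
#' @param values numeric option-level values.
#' @param scenario two-level factor/character (per option, constant within
#'   event).
#' @param eventId event identifier per option.
#' @param nPerm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `delta` (observed difference of means), `p` (two-sided),
#'   `nPerm`, `groups`.
#' @export
permutationMeanDiff <- function(values, scenario, eventId, nPerm = 9999,
                                seed = 1L) {
  ok <- !is.na(values)
  values <- values[ok]; scenario <- as.character(scenario)[ok]
  eventId <- as.character(eventId)[ok]
  lev <- unique(scenario)
  if (length(lev) != 2L) stop("scenario must have exactly two levels")
  evLab <- tapply(scenario, eventId, function(s) s[1])
  if (any(table(evLab) < 2L)) stop("need at least 2 events per scenario group")
  obs <- mean(values[scenario == lev[1]]) - mean(values[scenario == lev[2]])
  evs <- names(evLab)
  withSeed(seed, {
    perm <- vapply(seq_len(nPerm), function(b) {
      lab <- setNames(sample(evLab), evs)[eventId]
      mean(values[lab == lev[1]]) - mean(values[lab == lev[2]])
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1)
    list(delta = obs, p = p, nPerm = nPerm,
         groups = setNames(lev, c("first", "second")))
  })
}
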