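test_that("the power-model NLS agrees with the reference optimiser", {
  set.seed(14)
  P <- runif(150, 0.05, 1)
  y <- rbinom(150, 1, P^1.4)
  fit <- fitPowerNull(P, y)
  ref <- nls(y ~ P^a, start = list(a = 1))
  expect_equal(fit$a, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$se, summary(ref)$coefficients[1, 2], tolerance = 1e-3)
  expect_equal(fit$t, (fit$a - 1) / fit$se)
  expect_equal(fit$df, length(P) - 1L)
  expect_equal(fit$p, 2 * pt(-abs(fit$t), fit$df))
})

test_that("degenerate power-model inputs fail loudly", {
  expect_error(fitPowerNull(rep(1, 20), rep(1, 20)), "unidentifiable")
  expect_error(fitPowerNull(c(0.5, 0.6), c(1, 0)), "too few")
  # P = 0 events are excluded by default but can be kept
  P <- c(rep(0, 5), runif(50, 0.2, 0.9))
  y <- c(rep(0, 5), rbinom(50, 1, P[-(1:5)]))
  f1 <- fitPowerNull(P, y)
  expect_equal(f1$n, 50L)
  f2 <- fitPowerNull(P, y, includeZeroP = TRUE)
  expect_equal(f2$n, 55L)
})

test_that("the a = 1 test is calibrated and recovers a planted exponent", {
  ch <- defaultChoices()
  Pv <- ch$events$P[ch$events$P > 0]
  set.seed(52)
  ah <- pv <- a2 <- numeric(60)
  for (r in 1:60) {
    P <- sample(Pv, 276, replace = TRUE)
    f <- fitPowerNull(P, rbinom(276, 1, P))
    ah[r] <- f$a; pv[r] <- f$p
    a2[r] <- fitPowerNull(P, rbinom(276, 1, P^2))$a
  }
  expect_lt(abs(mean(ah) - 1), 0.06)
  expect_lt(mean(pv < 0.05), 0.15)
  expect_lt(abs(mean(a2) - 2), 0.1)
})

test_that("the decision logistic matches brute-force likelihood maximisation", {
  set.seed(8)
  d <- data.frame(nOptions = rpois(20, 3) + 1, nRegular = rpois(20, 5) + 1)
  eta <- -1 + 0.5 * scale(d$nOptions)[, 1]
  d$y <- rbinom(20, 1, plogis(eta))
  fit <- fitDecisionModel(d, predictors = c("nOptions"))
  # independent oracle: direct maximisation of the Bernoulli likelihood
  x <- scale(d$nOptions)[, 1]
  nll <- function(b) -sum(d$y * (b[1] + b[2] * x) -
                            log(1 + exp(b[1] + b[2] * x)))
  o <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(fit$coef$estimate), unname(o$par), tolerance = 1e-4)
})

test_that("constant predictors are dropped with a flag", {
  d <- data.frame(y = rbinom(30, 1, 0.5), a = rnorm(30), b = rep(2, 30))
  fit <- fitDecisionModel(d, predictors = c("a", "b"))
  expect_true("b" %in% fit$dropped)
  expect_match(paste(fit$flags, collapse = " "), "constant")
  expect_error(fitDecisionModel(data.frame(y = rbinom(10, 1, .5),
                                           a = rep(1, 10)),
                                predictors = "a"),
               "no usable")
})

test_that("conditional-logit probabilities are uniform without contrasts", {
  op <- data.frame(eventId = rep(1:4, each = 3),
                   chosen = rep(c(TRUE, FALSE, FALSE), 4),
                   x = rep(1, 12))  # constant within and across events
  fit <- fitPartnerModel(op, covariates = "x")
  expect_equal(unname(fit$probs), rep(1/3, 12))
  expect_equal(fit$coef$estimate, 0, tolerance = 1e-8)
})

test_that("two-option conditional logit equals paired logistic regression", {
  set.seed(23)
  nEv <- 80
  op <- do.call(rbind, lapply(seq_len(nEv), function(e) {
    x <- rnorm(2); z <- rnorm(2)
    u <- 1.2 * x - 0.7 * z
    pr <- exp(u) / sum(exp(u))
    ch <- sample(1:2, 1, prob = pr)
    data.frame(eventId = e, chosen = seq_len(2) == ch, x = x, z = z)
  }))
  fit <- fitPartnerModel(op, covariates = c("x", "z"))
  # algebraic oracle: logistic on within-event covariate differences
  d1 <- op[op$chosen, ]; d0 <- op[!op$chosen, ]
  dx <- d1$x - d0$x; dz <- d1$z - d0$z
  ref <- glm(rep(1, nEv) ~ 0 + dx + dz, family = binomial())
  expect_equal(unname(fit$coef$estimate), unname(coef(ref)), tolerance = 1e-4)
  # cross-check against the survival package's conditional logit
  if (requireNamespace("survival", quietly = TRUE)) {
    suppressMessages(library(survival))
    cl <- survival::clogit(chosen ~ x + z + strata(eventId), data = op)
    expect_equal(unname(fit$coef$estimate), unname(coef(cl)), tolerance = 1e-4)
    expect_equal(unname(fit$coef$se),
                 unname(summary(cl)$coefficients[, "se(coef)"]),
                 tolerance = 1e-3)
  }
  # per-event probabilities sum to one
  expect_equal(as.vector(tapply(fit$probs, op$eventId, sum)),
               rep(1, nEv), tolerance = 1e-10)
})

test_that("preference-mode simulations recover the planted choice weights", {
  cfg <- simConfig(seed = 5, decisionMode = "preference")
  col <- cached("prefColony", simulateColony(cfg))
  tr <- simTruth(col)
  op <- tr$options
  op$pupAgeS <- op$pupAge / 16
  op$assocSc <- op$assocS / 1800
  chosenEv <- unique(op$eventId[op$chosen])
  fit <- fitPartnerModel(op[op$eventId %in% chosenEv, ],
                         covariates = c("pupAgeS", "assocSc", "pedigreeR"))
  w <- cfg$preferenceWeights$partner
  est <- setNames(fit$coef$estimate, fit$coef$term)
  se <- setNames(fit$coef$se, fit$coef$term)
  expect_lt(abs(est["pupAgeS"] - w[["pupAge"]]), 2 * se["pupAgeS"])
  expect_lt(abs(est["assocSc"] - w[["association"]]), 2 * se["assocSc"])
  expect_lt(abs(est["pedigreeR"] - w[["relatedness"]]), 2 * se["pedigreeR"])
  expect_lt(est["pupAgeS"], 0)
  expect_gt(est["assocSc"], 0)
  # decision model: positive effect of the number of options
  dec <- tr$decisions[tr$decisions$nOptions > 0, ]
  dfit <- fitDecisionModel(dec, predictors = c("nOptions", "nRegular"))
  expect_gt(dfit$coef$estimate[dfit$coef$term == "nOptions"], 0)
})

test_that("the rank-sum test matches enumeration and the base implementation", {
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)         # 2 / choose(6, 3)
  expect_equal(r$W, 0)
  # shift invariance
  r2 <- mannWhitney(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(r2$p, r$p)
  # agrees with wilcox.test where both are exact (no ties)
  set.seed(3)
  for (k in 1:10) {
    a <- sample(seq(1, 199, 2), 6); b <- sample(seq(2, 200, 2), 7)
    ours <- mannWhitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$W, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # ties: midranks and a defined p
  rt <- mannWhitney(c(1, 2, 2, 3), c(2, 3, 4, 4))
  expect_equal(rt$W, sum(outer(c(1,2,2,3), c(2,3,4,4), ">")) +
                 0.5 * sum(outer(c(1,2,2,3), c(2,3,4,4), "==")))
  expect_true(rt$p > 0 && rt$p <= 1)
  # large samples switch to the tie-corrected normal approximation
  big <- mannWhitney(rnorm(60), rnorm(70))
  expect_match(big$method, "normal")
  expect_error(mannWhitney(numeric(0), 1:3), "empty")
})

test_that("the scenario permutation test respects event nesting", {
  set.seed(77)
  nEv <- 60
  evSc <- rep(c("communal", "solitary"), length.out = nEv)
  op <- do.call(rbind, lapply(seq_len(nEv), function(e) {
    k <- sample(2:4, 1)
    mu <- if (evSc[e] == "communal") 0.25 else 0.15
    data.frame(eventId = e, scenario = evSc[e], r = rnorm(k, mu, 0.15))
  }))
  res <- permutationMeanDiff(op$r, op$scenario, op$eventId, nPerm = 999,
                             seed = 5)
  expect_gt(res$delta, 0)
  expect_lt(res$p, 0.05)
  # identical groups: no signal
  op$r0 <- rnorm(nrow(op), 0.2, 0.1)
  res0 <- permutationMeanDiff(op$r0, op$scenario, op$eventId, nPerm = 999,
                              seed = 5)
  expect_gt(res0$p, 0.1)
  expect_error(permutationMeanDiff(1:4, rep(c("a", "b"), 2), 1:4,
                                   nPerm = 9, seed = 1),
               NA)
})
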