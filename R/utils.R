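#' @importFrom stats rbinom rexp rgamma rlnorm rpois runif rnorm quantile
#'   pt pnorm sd cor coef glm binomial optimize setNames aggregate vcov
#'   logLik complete.cases
#' @importFrom utils head tail combn packageVersion
#' @import methods
NULL

# Seconds per day; all event times are integer-valued seconds from the dataset
# epoch (day 0 = 2008-01-01 00:00:00), dates are integer day numbers.
DAY_S <- 86400

#' Convert a day number to an ISO-8601 date
#'
#' Day 0 corresponds to the dataset epoch 2008-01-01.
#'
#' @param day integer day number(s).
#' @return `Date` vector.
#' @export
dayToDate <- function(day) as.Date("2008-01-01") + day

#' Convert an ISO-8601 date to a day number
#'
#' @param date `Date` or character vector.
#' @return integer day number(s) since the 2008-01-01 epoch.
#' @export
dateToDay <- function(date) as.integer(as.Date(date) - as.Date("2008-01-01"))

# Calendar year cohort used for reference allele frequencies.
dayToYear <- function(day) 2008L + as.integer(day %/% 365)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. A NULL seed leaves the RNG alone.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed (< 2^31) from a master seed and a stage
# label, so each pipeline stage consumes an independent stream.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9349) %% 2147483587) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# data.table non-standard evaluation symbols
utils::globalVariables(c("tag", "entry_s", "exit_s", "box", ".N", ".I", ".SD",
                         "secs", "visits", "time_s"))
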