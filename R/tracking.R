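#' @importFrom data.table as.data.table setkey data.table rbindlist :=
NULL

# Keyed copy of an event log for repeated per-tag queries.
eventsDT <- function(events) {
  dt <- data.table::as.data.table(events)
  data.table::setkey(dt, tag, entry_s)
  dt
}

# Stays of one tag clipped to [lo, hi) seconds; assumes a keyed events DT.
staysClipped <- function(dt, id, lo, hi) {
  s <- dt[data.table::data.table(tag = id), nomatch = NULL]
  s <- s[exit_s > lo & entry_s < hi]
  if (!nrow(s)) return(s)
  s[, `:=`(entry_s = pmax(entry_s, lo), exit_s = pmin(exit_s, hi))]
  s
}

#' Stays of a female within a time window
#'
#' Stays partially overlapping the window are clipped to it, so a stay only
#' contributes its in-window part. An unknown female yields an empty result
#' with a warning.
#'
#' @param events event log data.frame (tag, box, entry_s, exit_s).
#' @param female tag id.
#' @param window numeric length-2, `[start_s, end_s)` in seconds.
#' @return data.frame of clipped stays.
#' @export
staysInWindow <- function(events, female, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (!female %in% events$tag) {
    warning("unknown female: ", female)
    return(events[0, ])
  }
  as.data.frame(staysClipped(eventsDT(events), female, window[1], window[2]))
}

# Internal home-area computation on a keyed DT.
homeAreaDT <- function(dt, female, birthDay, trackingWindowDays, minStayS) {
  lo <- (birthDay - trackingWindowDays) * DAY_S
  hi <- birthDay * DAY_S
  s <- staysClipped(dt, female, lo, hi)
  if (!nrow(s)) {
    boxSeconds <- numeric(0); boxVisits <- integer(0)
  } else {
    agg <- s[, .(secs = sum(exit_s - entry_s), visits = .N), by = box][order(box)]
    boxSeconds <- setNames(as.numeric(agg$secs), agg$box)
    boxVisits <- setNames(agg$visits, agg$box)
  }
  regular <- as.integer(names(boxSeconds)[boxSeconds >= minStayS])
  structure(list(female = female, birthDay = birthDay,
                 window = c(lo, hi), regularBoxes = regular,
                 boxSeconds = boxSeconds, boxVisits = boxVisits,
                 minStayS = minStayS),
            class = "homeArea")
}

#' Home area of a female before a birth
#'
#' The home area is the set of nest boxes the female entered for a cumulated
#' total of at least `minStayS` seconds (default 300 s, inclusive) during the
#' `trackingWindowDays`-day window ending at the birth instant (the birth day
#' itself excluded: the window is `[birth - 30 d, birth)`).
#'
#' @inheritParams staysInWindow
#' @param birthDay integer day of the focal birth.
#' @param trackingWindowDays window length in days (default 30).
#' @param minStayS regular-use threshold in seconds (default 300, inclusive).
#' @return object of class `homeArea` with elements `regularBoxes`,
#'   `boxSeconds`, `boxVisits`, `window`.
#' @export
homeArea <- function(events, female, birthDay, trackingWindowDays = 30,
                     minStayS = 300) {
  if (!female %in% events$tag) warning("no events for female ", female)
  homeAreaDT(eventsDT(events), female, birthDay, trackingWindowDays, minStayS)
}

#' @export
print.homeArea <- function(x, ...) {
  cat(sprintf("homeArea of %s before day %d: %d regular boxes (%s)\n",
              x$female, x$birthDay, length(x$regularBoxes),
              paste(x$regularBoxes, collapse = ", ")))
  invisible(x)
}

# Merge a set of disjoint-or-touching intervals and return count and total
# length; intervals given as two-column matrix (start, end).
mergeIntervals <- function(ivl) {
  if (!nrow(ivl)) return(list(n = 0L, total = 0))
  o <- order(ivl[, 1])
  s <- ivl[o, 1]; e <- ivl[o, 2]
  grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]))))
  list(n = max(grp),
       total = sum(e - s))
}

# Meetings of two tags on a keyed DT.
meetingsDT <- function(dt, a, b, lo, hi) {
  sa <- staysClipped(dt, a, lo, hi)
  sb <- staysClipped(dt, b, lo, hi)
  perBox <- list()
  count <- 0L; total <- 0
  if (nrow(sa) && nrow(sb)) {
    boxes <- intersect(unique(sa$box), unique(sb$box))
    for (bx in boxes) {
      xa <- sa[box == bx]; xb <- sb[box == bx]
      st <- outer(xa$entry_s, xb$entry_s, pmax)
      en <- outer(xa$exit_s, xb$exit_s, pmin)
      keep <- en > st
      if (!any(keep)) next
      m <- mergeIntervals(cbind(st[keep], en[keep]))
      perBox[[as.character(bx)]] <- c(n = m$n, seconds = m$total)
      count <- count + m$n; total <- total + m$total
    }
  }
  structure(list(pair = sort(c(a, b)), window = c(lo, hi),
                 count = count, seconds = total, perBox = perBox),
            class = "dyadAssociation")
}

#' Meetings and association time of a female dyad
#'
#' A meeting is a maximal time interval during which both females are
#' simultaneously inside the same nest box; association time is the summed
#' duration of all meetings within the window. Meetings of zero length
#' (shared boundary instant only) are not counted. The measure is symmetric
#' in the pair.
#'
#' @inheritParams staysInWindow
#' @param a,b the two tag ids (must differ).
#' @return object of class `dyadAssociation` with `count`, `seconds` and a
#'   per-box breakdown.
#' @export
meetings <- function(events, a, b, window) {
  if (identical(a, b)) stop("self-association is undefined")
  stopifnot(length(window) == 2L, window[2] > window[1])
  meetingsDT(eventsDT(events), a, b, window[1], window[2])
}

#' @export
print.dyadAssociation <- function(x, ...) {
  cat(sprintf("dyadAssociation %s - %s: %d meetings, %.0f s\n",
              x$pair[1], x$pair[2], x$count, x$seconds))
  invisible(x)
}

#' Dyadic association table over per-female windows
#'
#' For every ordered (focal, partner) pair of the supplied females, meetings
#' and association seconds are computed over the focal's own window (anchored
#' to her birth date), mirroring the tracking protocol in which association is
#' always measured in the 30 days before the focal birth. The result is
#' invariant to the row order of the event log.
#'
#' @inheritParams staysInWindow
#' @param windows data.frame(female, start_s, end_s): one window per focal
#'   female.
#' @param partners optional character vector of partner ids; default all
#'   females in `windows`.
#' @return data.frame(focal, partner, start_s, end_s, meetings, seconds).
#' @export
associationMatrix <- function(events, windows, partners = NULL) {
  dt <- eventsDT(events)
  if (is.null(partners)) partners <- windows$female
  out <- vector("list", nrow(windows) * length(partners))
  k <- 0L
  for (i in seq_len(nrow(windows))) {
    for (p in partners) {
      if (identical(p, windows$female[i])) next
      m <- meetingsDT(dt, windows$female[i], p,
                      windows$start_s[i], windows$end_s[i])
      k <- k + 1L
      out[[k]] <- data.frame(focal = windows$female[i], partner = p,
                             start_s = windows$start_s[i],
                             end_s = windows$end_s[i],
                             meetings = m$count, seconds = m$seconds)
    }
  }
  if (!k) return(data.frame(focal = character(), partner = character(),
                            start_s = numeric(), end_s = numeric(),
                            meetings = integer(), seconds = numeric()))
  do.call(rbind, out[seq_len(k)])
}

#' Pair single-antenna reads into stays
#'
#' Raw paired entry/exit records are the canonical event-log input. For
#' installations logging bare reads, this adapter pairs each read with the
#' next read of the same tag at the same box into one stay, capping the
#' implied stay at `maxStayS` seconds (a lone read, or a gap beyond the cap,
#' yields a capped stay flagged in the output — never silently). The result
#' satisfies the event-log invariants.
#'
#' @param reads data.frame(tag, box, time_s) of antenna reads.
#' @param maxStayS cap on the implied stay duration (default 4 hours).
#' @return data.frame(tag, box, entry_s, exit_s, capped) of stays.
#' @export
pairAntennaReads <- function(reads, maxStayS = 4 * 3600) {
  dt <- data.table::as.data.table(reads)[order(tag, time_s)]
  out <- dt[, {
    n <- .N
    odd <- seq_len(n) %% 2L == 1L
    entry <- time_s[odd]
    exit <- rep(NA_real_, length(entry))
    exit[seq_len(sum(!odd))] <- time_s[!odd]
    capped <- is.na(exit) | (exit - entry) > maxStayS
    exit <- pmin(exit, entry + maxStayS, na.rm = TRUE)
    list(entry_s = entry, exit_s = exit, capped = capped)
  }, by = .(tag, box)]
  if (any(out$capped))
    warning(sum(out$capped), " read pair(s) exceeded the stay cap or were ",
            "unpaired; stays capped at ", maxStayS, " s")
  out <- out[exit_s > entry_s]
  as.data.frame(out[order(tag, entry_s)])
}
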