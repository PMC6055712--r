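# Independent brute-force oracles, kept deliberately naive: day-by-day
# simulation on an explicit grid rather than interval arithmetic.

# exposed-day set of an interval list
days_covered <- function(start, stop) {
  if (!length(start)) return(integer(0))
  sort(unique(unlist(Map(function(s, e) if (e > s) seq(s, e - 1L) else
    integer(0), start, stop))))
}

# day-by-day stock simulation: every prescription adds `dur` days of supply
# at its start; one day of supply is consumed per exposed day. Models both
# stockpiling (9a) and duration-summing (9d), which cover identical days.
oracle_stock_days <- function(start, stop) {
  if (!length(start)) return(integer(0))
  dur <- stop - start
  horizon <- max(start) + sum(dur) + 1L
  stock <- 0
  exposed <- integer(0)
  for (d in min(start):horizon) {
    stock <- stock + sum(dur[start == d])
    if (stock > 0) {
      exposed <- c(exposed, d)
      stock <- stock - 1
    }
  }
  exposed
}

# 9b: a day is covered by an episode unless some strictly later-starting
# episode has already begun by that day
oracle_truncate_days <- function(start, stop) {
  if (!length(start)) return(integer(0))
  all_days <- days_covered(start, stop)
  keep <- vapply(all_days, function(d) {
    any(vapply(seq_along(start), function(i) {
      start[i] <= d && d < stop[i] &&
        !any(start > start[i] & start <= d)
    }, logical(1)))
  }, logical(1))
  all_days[keep]
}

# 9e: walk episodes in start order; an episode whose start day is already
# exposed is discarded outright
oracle_droplater_days <- function(start, stop) {
  o <- order(start, stop)
  exposed <- integer(0)
  for (i in o) {
    if (!(start[i] %in% exposed) && stop[i] > start[i])
      exposed <- union(exposed, seq(start[i], stop[i] - 1L))
  }
  sort(exposed)
}

# 10b(x): fill every unexposed run strictly shorter than x days that lies
# between exposed days
oracle_bridge_days <- function(days, x) {
  if (length(days) < 2L) return(days)
  days <- sort(days)
  out <- days
  gaps <- which(diff(days) > 1L)
  for (g in gaps) {
    gap_len <- days[g + 1L] - days[g] - 1L
    if (gap_len < x) out <- c(out, seq(days[g] + 1L, days[g + 1L] - 1L))
  }
  sort(unique(out))
}

oracle_span_days <- function(days) {
  if (!length(days)) return(integer(0))
  seq(min(days), max(days))
}

oracle_node9_days <- function(start, stop, letter) {
  switch(letter,
         a = oracle_stock_days(start, stop),
         b = oracle_truncate_days(start, stop),
         c = days_covered(start, stop),
         d = oracle_stock_days(start, stop),
         e = oracle_droplater_days(start, stop))
}

# scalar transliteration of the stop-date reconciliation footnote:
# one candidate -> use it; two equal -> that date; two unequal within x ->
# mean; three not all equal -> mean of closest pair if within x; ties on
# closeness prefer the pair containing the qty/ndd candidate
oracle_reconcile <- function(nd, dd, qn, x) {
  cand <- c(nd = nd, dd = dd, qn = qn)
  present <- cand[!is.na(cand)]
  if (length(present) == 0L) return(NA_integer_)
  if (length(present) == 1L) return(as.integer(present))
  mean_day <- function(a, b) as.integer(floor((a + b) / 2 + 0.5))
  if (length(present) == 2L) {
    if (present[1] == present[2]) return(as.integer(present[1]))
    if (abs(present[1] - present[2]) <= x)
      return(mean_day(present[1], present[2]))
    return(NA_integer_)
  }
  if (length(unique(present)) == 1L) return(as.integer(present[1]))
  pair_names <- list(c("nd", "qn"), c("dd", "qn"), c("nd", "dd"))
  dists <- vapply(pair_names, function(p) abs(cand[p[1]] - cand[p[2]]),
                  numeric(1))
  best <- pair_names[[which.min(dists)]]
  if (min(dists) <= x) return(mean_day(cand[best[1]], cand[best[2]]))
  NA_integer_
}

# random disjoint-ish episode sets for property tests
random_episodes <- function(n, max_start = 60L, max_dur = 30L) {
  s <- sample.int(max_start, n, replace = TRUE)
  d <- sample.int(max_dur, n, replace = TRUE)
  o <- order(s, s + d)
  list(start = as.integer(s[o]), stop = as.integer(s[o] + d[o]))
}
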