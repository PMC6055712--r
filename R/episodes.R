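#' Step C: from dated prescriptions to exposure episodes
#'
#' After Step B every record carries a half-open interval
#' `[start_date, stop_date)`. Node 8 collapses same-day duplicates within a
#' product; the records are then lifted to exposure episodes within a drug
#' class, node 9 resolves overlaps, node 10 closes short gaps, and the final
#' timeline is clipped to each patient's follow-up window. Overlap and gap
#' resolution operate within drug class (not product code): a class is the
#' unit of the downstream exposure contrast.
#'
#' @name episodes
NULL

#' Collapse same-day duplicate prescriptions (node 8)
#'
#' Within each (patient, product, start date) group holding more than one
#' record: 8a keeps the longest duration, 8b the shortest, 8c replaces the
#' group by one record with the summed duration, 8d by one record with the
#' mean duration (rounded half-up), and 8e keeps the group intact and defers
#' to node 9. Non-duration columns of a collapsed group are taken from its
#' first record.
#'
#' @inheritParams clean_quantity
#' @param node8_option option token for node 8
#' @return the therapy table with at most one record per group (except 8e)
#' @export
collapse_same_day <- function(records, node8_option, ledger = NULL) {
  letter <- .option_letter(node8_option, 8L)
  dt <- as_therapy(records)
  if (!"stop_date" %in% names(dt) || anyNA(dt$stop_date))
    stop("all records must have stop dates before node 8")
  n <- nrow(dt)
  if (letter == "e") {
    ledger_add(ledger, "8", n)
    return(dt[])
  }
  dt[, duration := as.numeric(stop_date - start_date)]
  dt[, .row := .I]
  setorder(dt, patient_id, product_code, start_date, .row)
  grp_cols <- c("patient_id", "product_code", "start_date")
  sizes <- dt[, .N, by = grp_cols]
  n_groups_multi <- sizes[N > 1L, .N]
  agg <- switch(letter,
    a = dt[, .(.d = max(duration)), by = grp_cols],
    b = dt[, .(.d = min(duration)), by = grp_cols],
    c = dt[, .(.d = sum(duration)), by = grp_cols],
    d = dt[, .(.d = round_half_up(mean(duration))), by = grp_cols])
  out <- dt[dt[, .I[1L], by = grp_cols]$V1]
  out[agg, on = grp_cols, duration := i..d]
  out[, stop_date := as.integer(start_date + duration)]
  setorder(out, .row)
  out[, c("duration", ".row") := NULL]
  ledger_add(ledger, "8", n, records_modified = n_groups_multi,
             records_dropped = n - nrow(out))
  out[]
}

#' Lift dated prescription records to exposure episodes
#'
#' Maps each record's product code to its drug class (via the plausibility
#' table's `drug_class` column; products without an entry keep their product
#' code as class) and returns sorted episodes `[start, stop)`.
#'
#' @inheritParams clean_quantity
#' @return episode `data.table` with columns `patient_id`, `drug_class`,
#'   `start`, `stop`
#' @export
records_to_episodes <- function(records, plausibility = NULL) {
  dt <- as_therapy(records)
  if (!"stop_date" %in% names(dt) || anyNA(dt$stop_date))
    stop("all records must have stop dates")
  if (!is.null(plausibility)) {
    pl <- as_plausibility(plausibility)[, .(product_code, drug_class)]
    dt <- pl[dt, on = "product_code"]
    dt[is.na(drug_class), drug_class := product_code]
  } else {
    dt[, drug_class := product_code]
  }
  ep <- dt[, .(patient_id, drug_class, start = as.integer(start_date),
               stop = as.integer(stop_date))]
  setorder(ep, patient_id, drug_class, start, stop)
  ep[]
}

# per-group (already sorted by start) overlap resolution; returns a
# data.table(start, stop, modified, dropped) where modified/dropped are
# scalar counts replicated for convenience
.resolve_group <- function(start, stop, letter) {
  n <- length(start)
  dur <- stop - start
  if (n == 1L)
    return(list(start = start, stop = stop, modified = 0L, dropped = 0L))
  switch(letter,
    a = { # stockpiling: e_i = max(start_i, e_{i-1}) + dur_i, vectorised
      cs <- cumsum(dur)
      f <- cummax(start - shift(cs, fill = 0L))
      e <- f + cs
      s <- e - dur
      list(start = as.integer(s), stop = as.integer(e),
           modified = sum(s != start), dropped = 0L)
    },
    b = { # truncate the earlier at the later's start
      s2 <- pmin(stop, shift(start, type = "lead", fill = .Machine$integer.max))
      keep <- s2 > start
      list(start = start[keep], stop = as.integer(s2[keep]),
           modified = sum(s2 < stop), dropped = sum(!keep))
    },
    c = { # merge to the interval union (strict overlap only)
      grp <- cumsum(c(TRUE, start[-1L] >= cummax(stop)[-n]))
      s <- tapply(start, grp, min)
      e <- tapply(stop, grp, max)
      list(start = as.integer(s), stop = as.integer(e),
           modified = sum(tabulate(grp) > 1L), dropped = n - length(s))
    },
    d = { # sum durations from the earliest start of each overlapping chain
      s_out <- integer(0); e_out <- integer(0)
      cur_s <- start[1L]; cur_e <- start[1L] + dur[1L]
      merged <- FALSE; n_merged_chains <- 0L
      for (i in seq_len(n)[-1L]) {
        if (start[i] < cur_e) {
          cur_e <- cur_e + dur[i]
          merged <- TRUE
        } else {
          s_out <- c(s_out, cur_s); e_out <- c(e_out, cur_e)
          if (merged) n_merged_chains <- n_merged_chains + 1L
          cur_s <- start[i]; cur_e <- start[i] + dur[i]; merged <- FALSE
        }
      }
      s_out <- c(s_out, cur_s); e_out <- c(e_out, cur_e)
      if (merged) n_merged_chains <- n_merged_chains + 1L
      list(start = s_out, stop = e_out, modified = n_merged_chains,
           dropped = n - length(s_out))
    },
    e = { # drop the later overlapping record
      keep <- logical(n)
      cur_e <- -.Machine$integer.max
      for (i in seq_len(n)) {
        if (start[i] >= cur_e) {
          keep[i] <- TRUE
          cur_e <- stop[i]
        }
      }
      list(start = start[keep], stop = stop[keep], modified = 0L,
           dropped = sum(!keep))
    },
    stop("unknown node-9 option letter: ", letter))
}

#' Resolve overlapping prescriptions (node 9)
#'
#' Episodes of one patient and drug class are processed in start order with
#' a running exposure end. 9a *stockpiling*: an overlapping later episode is
#' delayed to the running end with its duration preserved. 9b truncates the
#' earlier episode at the later's start. 9c merges strictly overlapping
#' episodes to their union (surplus supply discarded). 9d merges each
#' overlapping chain into a single episode from the earliest start whose
#' length is the sum of the chain's durations. 9e drops the later
#' overlapping record. The output is overlap-free; under 9a and 9d total
#' exposed days equal the sum of input durations, under 9b/9c/9e they can
#' only shrink.
#'
#' @param episodes episode table (`patient_id`, `drug_class`, `start`,
#'   `stop`), sorted by start within patient and class
#' @param node9_option option token for node 9
#' @param ledger optional [new_ledger()]
#' @return overlap-free sorted episode `data.table`
#' @examples
#' ep <- data.frame(patient_id = 1, drug_class = "d",
#'                  start = c(0, 14), stop = c(28, 42))
#' resolve_overlaps(ep, "9a")  # [0,28) and [28,56)
#' @export
resolve_overlaps <- function(episodes, node9_option, ledger = NULL) {
  letter <- .option_letter(node9_option, 9L)
  ep <- as.data.table(episodes)
  n <- nrow(ep)
  if (n == 0L) {
    ledger_add(ledger, "9", 0L)
    return(ep)
  }
  setorder(ep, patient_id, drug_class, start, stop)
  out <- ep[, .resolve_group(start, stop, letter),
            by = .(patient_id, drug_class)]
  modified <- out[, .(m = modified[1L]), by = .(patient_id, drug_class)][, sum(m)]
  out[, c("modified", "dropped") := NULL]
  ledger_add(ledger, "9", n, records_modified = modified,
             records_dropped = n - nrow(out))
  out[]
}

#' Close short gaps between successive episodes (node 10)
#'
#' 10a never bridges (a gap is unexposed time); 10b(x) treats exposure as
#' continuous when the gap between consecutive episodes is strictly less
#' than x days, merging left-to-right until stable; 10c treats the patient
#' as continuously exposed from first start to last stop of the class.
#'
#' @inheritParams resolve_overlaps
#' @param node10_option option token: `"10a"`, `"10b(x)"` or `"10c"`
#' @return gap-closed sorted episode `data.table`
#' @export
close_gaps <- function(episodes, node10_option, ledger = NULL) {
  letter <- .option_letter(node10_option, 10L)
  ep <- as.data.table(episodes)
  n <- nrow(ep)
  if (n == 0L || letter == "a") {
    ledger_add(ledger, "10", n)
    return(ep[])
  }
  setorder(ep, patient_id, drug_class, start, stop)
  if (letter == "b") {
    x <- option_param(node10_option)
    if (is.na(x)) stop("option 10b requires a day parameter, e.g. '10b(30)'")
    out <- ep[, {
      gap <- start - shift(cummax(stop))
      grp <- cumsum(is.na(gap) | gap >= x)
      .(start = tapply(start, grp, min), stop = tapply(stop, grp, max),
        merged = tabulate(grp) > 1L)
    }, by = .(patient_id, drug_class)]
  } else { # 10c
    out <- ep[, .(start = min(start), stop = max(stop), merged = .N > 1L),
              by = .(patient_id, drug_class)]
  }
  out[, `:=`(start = as.integer(start), stop = as.integer(stop))]
  modified <- sum(out$merged)
  out[, merged := NULL]
  ledger_add(ledger, "10", n, records_modified = modified,
             records_dropped = n - nrow(out))
  out[]
}

#' Clip episodes to the follow-up window
#'
#' Episodes are clipped to each patient's `[entry, exit)`; episodes entirely
#' outside follow-up are removed. The complement of the result within
#' follow-up is the patient's unexposed person-time.
#'
#' @param episodes episode table
#' @param followup table with `patient_id`, `entry`, `exit` (`exit > entry`)
#' @param ledger optional [new_ledger()]; a `"clip"` row is appended
#' @return disjoint sorted episode `data.table`, all within follow-up
#' @export
build_exposure_timeline <- function(episodes, followup, ledger = NULL) {
  ep <- as.data.table(episodes)
  fu <- as.data.table(followup)
  stopifnot(all(c("patient_id", "entry", "exit") %in% names(fu)))
  if (any(fu$exit <= fu$entry)) stop("follow-up requires exit > entry")
  n <- nrow(ep)
  out <- fu[, .(patient_id, entry, exit)][ep, on = "patient_id"]
  out <- out[!is.na(entry)]
  out[, `:=`(start = pmax(start, entry), stop = pmin(stop, exit))]
  out <- out[stop > start]
  out[, c("entry", "exit") := NULL]
  setcolorder(out, c("patient_id", "drug_class", "start", "stop"))
  setorder(out, patient_id, drug_class, start)
  ledger_add(ledger, "clip", n, records_dropped = n - nrow(out))
  out[]
}

#' Export a timeline as an exposed/unexposed interval CSV
#'
#' Writes one row per interval of follow-up: the prepared exposure episodes
#' (`exposed = 1`) and the derived unexposed complement (`exposed = 0`).
#'
#' @param timeline clipped episode table from [build_exposure_timeline()]
#' @param followup follow-up table (`patient_id`, `entry`, `exit`)
#' @param file output CSV path
#' @return the exported `data.table`, invisibly
#' @export
write_timeline <- function(timeline, followup, file) {
  rows <- split_person_time(timeline, followup)
  out <- rows[, .(patient_id, drug_class = state, start, stop,
                  exposed = as.integer(state != "unexposed"))]
  fwrite(out, file)
  invisible(out)
}
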