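#' Step B: deriving prescription stop dates
#'
#' The stop date of a prescription is not recorded and must be computed from
#' one of three duration sources: `numdays`, `dose_duration`, or the implied
#' duration `qty / ndd`. Node 6 chooses the source (or reconciles the
#' available candidates); node 7 resolves stop dates that are still missing,
#' and any record that leaves node 7 without a stop date is dropped.
#'
#' @name duration
NULL

#' Candidate stop dates for each prescription
#'
#' Computes the three candidate stop dates per record:
#' `stop_numdays = start_date + numdays`,
#' `stop_dose_duration = start_date + dose_duration`, and
#' `stop_qty_ndd = start_date + round(qty / ndd)` (half-up), each missing
#' when its source is missing. A candidate duration that rounds to zero (or
#' less) days becomes missing — a prescription must cover at least one day.
#'
#' @param records therapy table that has passed Step A
#' @return the table with integer columns `stop_numdays`,
#'   `stop_dose_duration`, `stop_qty_ndd` appended
#' @examples
#' rx <- data.frame(patient_id = 1, product_code = "P1", start_date = 0,
#'                  qty = 56, ndd = 2, numdays = NA, dose_duration = NA)
#' candidate_stop_dates(rx)$stop_qty_ndd  # day 28
#' @export
candidate_stop_dates <- function(records) {
  dt <- as_therapy(records)
  cand <- function(dur) {
    d <- round_half_up(dur)
    d[!is.na(d) & d <= 0] <- NA_real_
    as.integer(dt$start_date + d)
  }
  dt[, `:=`(
    stop_numdays = cand(numdays),
    stop_dose_duration = cand(dose_duration),
    stop_qty_ndd = cand(ifelse(!is.na(qty) & !is.na(ndd) & ndd > 0,
                               qty / ndd, NA_real_))
  )]
  dt[]
}

#' Select a stop date from the candidates (node 6)
#'
#' Options 6a/6b/6c return their single source (`numdays`, `dose_duration`,
#' `qty`/`ndd`), missing when that source is missing. Option 6d(x)
#' reconciles whatever candidates are available:
#'
#' * one candidate: use it;
#' * two, equal: that date; two, unequal but within x days: their mean;
#'   two, further apart than x days: missing;
#' * three, all equal: that date; three, not all equal: the mean of the
#'   closest pair if that pair is within x days, else missing;
#' * none: missing.
#'
#' Date means are means of integer day offsets rounded half-up, so the mean
#' of two dates an odd number of days apart is the later of the two middle
#' days. When two pairs are equally close, the pair involving the
#' `qty`/`ndd` candidate (the best-populated source) wins.
#'
#' @param candidates a table bearing `stop_numdays`, `stop_dose_duration`
#'   and `stop_qty_ndd` (as produced by [candidate_stop_dates()])
#' @param node6_option option token: `"6a"`, `"6b"`, `"6c"` or `"6d(x)"`
#' @return integer vector of stop dates (NA where unresolved)
#' @examples
#' cand <- data.frame(stop_numdays = 30, stop_dose_duration = NA,
#'                    stop_qty_ndd = 28)
#' select_stop_date(cand, "6d(15)")  # day 29
#' @export
select_stop_date <- function(candidates, node6_option) {
  if (option_node(node6_option) != 6L)
    stop("option '", node6_option, "' does not belong to node 6")
  cd <- as.data.table(candidates)
  need <- c("stop_numdays", "stop_dose_duration", "stop_qty_ndd")
  if (!all(need %in% names(cd)))
    stop("candidates must carry ", paste(need, collapse = ", "))
  base <- option_base(node6_option)
  if (base == "6a") return(as.integer(cd$stop_numdays))
  if (base == "6b") return(as.integer(cd$stop_dose_duration))
  if (base == "6c") return(as.integer(cd$stop_qty_ndd))
  x <- option_param(node6_option)
  if (is.na(x)) stop("option 6d requires a day tolerance, e.g. '6d(30)'")

  nd <- as.numeric(cd$stop_numdays)
  dd <- as.numeric(cd$stop_dose_duration)
  qn <- as.numeric(cd$stop_qty_ndd)
  m <- cbind(nd, dd, qn)
  npres <- rowSums(!is.na(m))
  out <- rep(NA_real_, nrow(m))

  one <- npres == 1L
  out[one] <- rowSums(m[one, , drop = FALSE], na.rm = TRUE)

  two <- npres == 2L
  if (any(two)) {
    hi <- apply(m[two, , drop = FALSE], 1L, max, na.rm = TRUE)
    lo <- apply(m[two, , drop = FALSE], 1L, min, na.rm = TRUE)
    res <- ifelse(hi - lo <= x, round_half_up((hi + lo) / 2), NA_real_)
    out[two] <- res
  }

  three <- npres == 3L
  if (any(three)) {
    # closest pair among the three; ties prefer pairs involving qty/ndd,
    # in the fixed order (numdays, qty/ndd), (dose_duration, qty/ndd),
    # (numdays, dose_duration)
    pairs <- list(c("nd", "qn"), c("dd", "qn"), c("nd", "dd"))
    vals <- list(nd = nd, dd = dd, qn = qn)
    d <- sapply(pairs, function(p)
      abs(vals[[p[1]]][three] - vals[[p[2]]][three]))
    d <- matrix(d, ncol = 3L)
    best <- max.col(-d, ties.method = "first")
    dmin <- d[cbind(seq_len(nrow(d)), best)]
    mean_pair <- sapply(seq_along(best), function(i) {
      p <- pairs[[best[i]]]
      idx <- which(three)[i]
      round_half_up((vals[[p[1]]][idx] + vals[[p[2]]][idx]) / 2)
    })
    all_eq <- d[, 1L] == 0 & d[, 2L] == 0 & d[, 3L] == 0
    res <- ifelse(all_eq, nd[three],
                  ifelse(dmin <= x, mean_pair, NA_real_))
    out[three] <- res
  }
  as.integer(out)
}

#' Assign stop dates (node 6 driver)
#'
#' Convenience wrapper: computes candidates and applies the node-6 option,
#' writing a `stop_date` column and a node-6 ledger row.
#'
#' @inheritParams clean_quantity
#' @param node6_option option token for node 6
#' @return the therapy table with an integer `stop_date` column (NA where
#'   unresolved); the candidate columns are removed
#' @export
assign_stop_dates <- function(records, node6_option, ledger = NULL) {
  dt <- candidate_stop_dates(records)
  stops <- select_stop_date(dt, node6_option)
  dt[, c("stop_numdays", "stop_dose_duration", "stop_qty_ndd") := NULL]
  dt[, stop_date := stops]
  ledger_add(ledger, "6", nrow(dt), records_modified = sum(!is.na(stops)))
  dt[]
}

#' Resolve missing stop dates (node 7)
#'
#' Records that reach node 7 without a stop date are handled by option:
#' 7a keep missing; 7b impute the patient's mean duration for that product;
#' 7c impute the population mean duration for that product; 7d impute the
#' product's `default_duration_days`; 7e carry forward the duration of the
#' patient's previous prescription for that product. Donor durations are the
#' observed `stop_date - start_date` of records that resolved a stop date at
#' node 6, and imputed durations are rounded half-up to whole days. The
#' imputation deliberately does not cascade to a broader donor pool: when
#' the option's own donor is unavailable the stop date stays missing, and
#' every record still missing a stop date at the end of the node is dropped
#' and counted in the ledger.
#'
#' @inheritParams clean_quantity
#' @param node7_option option token for node 7
#' @return the therapy table with all remaining records bearing a
#'   `stop_date`; records without one have been removed
#' @export
resolve_missing_stop <- function(records, node7_option, plausibility,
                                 ledger = NULL) {
  letter <- .option_letter(node7_option, 7L)
  dt <- as_therapy(records)
  if (!"stop_date" %in% names(dt))
    stop("records must carry a stop_date column (run assign_stop_dates first)")
  plausibility <- as_plausibility(plausibility)
  n <- nrow(dt)
  dt[, duration := as.numeric(stop_date - start_date)]
  miss <- which(is.na(dt$stop_date))
  imputed <- 0L
  if (length(miss) && letter != "a") {
    repl <- switch(letter,
      b = { # patient mean duration for the product
        agg <- dt[!is.na(duration), .(.stat = mean(duration)),
                  by = .(patient_id, product_code)]
        dt[agg, on = c("patient_id", "product_code"), .stat := i..stat]
        dt$.stat[miss]
      },
      c = { # population mean duration for the product
        agg <- dt[!is.na(duration), .(.stat = mean(duration)),
                  by = product_code]
        dt[agg, on = "product_code", .stat := i..stat]
        dt$.stat[miss]
      },
      d = { # product default duration
        pl <- plausibility[, .(product_code,
                               .def = as.numeric(default_duration_days))]
        dt[pl, on = "product_code", .def := i..def]
        dt$.def[miss]
      },
      e = { # duration of the previous prescription, same patient/product
        dt[, .row := .I]
        setorder(dt, patient_id, product_code, start_date, .row)
        gid <- rleidv(dt, cols = c("patient_id", "product_code"))
        dt[, .prev := .prev_in_group(as.numeric(duration), gid)]
        setorder(dt, .row)
        dt$.prev[miss]
      },
      stop("unknown node-7 option: ", node7_option))
    repl <- round_half_up(repl)
    repl[!is.na(repl) & repl <= 0] <- NA_real_
    fill <- miss[!is.na(repl)]
    set(dt, i = fill, j = "stop_date",
        value = as.integer(dt$start_date[fill] + repl[!is.na(repl)]))
    imputed <- length(fill)
  }
  drop <- is.na(dt$stop_date)
  out <- dt[!drop]
  drop_cols <- intersect(c(".stat", ".def", ".prev", ".row", "duration"),
                         names(out))
  if (length(drop_cols)) out[, (drop_cols) := NULL]
  ledger_add(ledger, "7", n, records_modified = imputed,
             records_dropped = sum(drop))
  out[]
}
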