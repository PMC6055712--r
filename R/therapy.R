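#' Therapy and plausibility tables
#'
#' The raw input is a *therapy* table of prescription records with one row
#' per issued prescription:
#'
#' * `patient_id` — opaque patient identifier
#' * `product_code` — opaque product identifier (pack-level granularity)
#' * `start_date` — integer day offset from the study epoch (always present)
#' * `qty` — total quantity of units issued (may be missing)
#' * `ndd` — numeric daily dose, units per day (may be missing)
#' * `numdays` — prescriber-entered treatment days (may be missing)
#' * `dose_duration` — database-derived duration in days (may be missing)
#'
#' Dates are integer day offsets throughout; there is no time of day. All
#' intervals are half-open `[start, stop)`: a one-day prescription has
#' `stop = start + 1` and length in days is `stop - start`.
#'
#' The *plausibility* table holds per-product clinical plausibility bounds
#' and fallback defaults: `product_code`, `qty_min`, `qty_max`, `ndd_min`,
#' `ndd_max`, `dur_min`, `dur_max`, `default_qty`, `default_ndd`,
#' `default_duration_days`, and (optionally) `drug_class`, the class label
#' under which Step C builds exposure episodes. Bounds are inclusive: a value
#' equal to a bound is plausible.
#'
#' @param x a data.frame-like therapy table
#' @return `as_therapy()` returns a validated `data.table` copy.
#' @export
as_therapy <- function(x) {
  need <- c("patient_id", "product_code", "start_date", "qty", "ndd",
            "numdays", "dose_duration")
  dt <- as.data.table(x)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("therapy table lacks columns: ", paste(missing_cols, collapse = ", "))
  dt <- copy(dt)
  for (col in c("qty", "ndd", "numdays", "dose_duration"))
    set(dt, j = col, value = as.numeric(dt[[col]]))
  set(dt, j = "start_date", value = as.integer(dt$start_date))
  if (anyNA(dt$start_date)) stop("start_date must always be present")
  bad <- function(v) any(!is.na(v) & (!is.finite(v) | v < 0))
  for (col in c("qty", "ndd", "numdays", "dose_duration"))
    if (bad(dt[[col]])) stop(col, " must be missing or finite and >= 0")
  if ("stop_date" %in% names(dt)) {
    set(dt, j = "stop_date", value = as.integer(dt$stop_date))
    if (any(!is.na(dt$stop_date) & dt$stop_date < dt$start_date))
      stop("stop_date must be >= start_date")
  }
  dt
}

#' @rdname as_therapy
#' @export
as_plausibility <- function(x) {
  need <- c("product_code", "qty_min", "qty_max", "ndd_min", "ndd_max",
            "dur_min", "dur_max", "default_qty", "default_ndd",
            "default_duration_days")
  dt <- as.data.table(x)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("plausibility table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  dt <- copy(dt)
  if (anyDuplicated(dt$product_code))
    stop("duplicate product_code in plausibility table")
  for (pair in list(c("qty_min", "qty_max"), c("ndd_min", "ndd_max"),
                    c("dur_min", "dur_max"))) {
    lo <- dt[[pair[1]]]; hi <- dt[[pair[2]]]
    if (any(lo > hi, na.rm = TRUE)) stop(pair[1], " > ", pair[2])
    if (any(c(lo, hi) <= 0, na.rm = TRUE)) stop("bounds must be > 0")
  }
  within <- function(v, lo, hi) is.na(v) | (v >= lo & v <= hi)
  if (!all(within(dt$default_qty, dt$qty_min, dt$qty_max)) ||
      !all(within(dt$default_ndd, dt$ndd_min, dt$ndd_max)) ||
      !all(within(dt$default_duration_days, dt$dur_min, dt$dur_max)))
    stop("defaults must lie within their own bounds")
  if (!"drug_class" %in% names(dt))
    set(dt, j = "drug_class", value = dt$product_code)
  dt
}

# Left-join per-product columns from the plausibility table onto records.
# Products absent from the table get NA bounds, which downstream code treats
# as "everything plausible" (with a warning emitted by the caller).
.join_plaus <- function(records, plausibility, cols) {
  pl <- plausibility[, c("product_code", cols), with = FALSE]
  out <- pl[records, on = "product_code"]
  setcolorder(out, c(setdiff(names(out), cols), cols))
  out
}

.warn_unknown_products <- function(records, plausibility) {
  unk <- setdiff(unique(records$product_code), plausibility$product_code)
  if (length(unk))
    warning("no plausibility entry for product(s) ",
            paste(head(unk, 5), collapse = ", "),
            if (length(unk) > 5) ", ..." else "",
            "; all their values treated as plausible", call. = FALSE)
  invisible(unk)
}
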