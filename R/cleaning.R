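#' Step A: cleaning quantity, daily dose and duration fields
#'
#' Nodes 1-5 correct clinically implausible values and impute missing values
#' of `qty`, `ndd`, `numdays` and `dose_duration` against per-product
#' plausibility bounds. Imputation statistics (population and patient means,
#' carry-forward donors) are computed once per node from a frozen snapshot
#' of that node's input, restricted to plausible (in-bounds, non-missing)
#' values, so results do not depend on the order in which records are
#' visited within a node and cleaning is idempotent. "Population" means
#' within the supplied dataset, per product code; when a product has no
#' plausible donor values the product default from the plausibility table is
#' used, and a carry-forward option with no prior prescription leaves the
#' value missing. No record is ever dropped in Step A.
#'
#' @name cleaning
NULL

.mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

# Last non-missing value of an earlier row within (already sorted) groups:
# a single global last-observation-carried-forward with group resets.
.prev_in_group <- function(values, group_id) {
  pos <- seq_along(values)
  pos[is.na(values)] <- NA_integer_
  pos <- shift(pos)
  if (!all(is.na(pos))) pos <- nafill(pos, type = "locf")
  ok <- !is.na(pos) & group_id[pmax(pos, 1L)] == group_id
  out <- rep(NA_real_, length(values))
  out[ok] <- values[pos[ok]]
  out
}

# Attach per-product bounds/default and pre-cleaning snapshot statistics for
# one field: .lo/.hi/.def, .plaus, and on demand (`need`) .pop (population
# mean of plausible values per product), .pat (patient x product mean),
# .prev (last plausible value of an earlier prescription, same patient and
# product). Statistics are taken from the snapshot before any value changes.
.prep_field <- function(records, plausibility, field, lo, hi, def,
                        need = character()) {
  dt <- copy(records)
  pl <- plausibility[, .(product_code, .lo = get(lo), .hi = get(hi),
                         .def = as.numeric(get(def)))]
  dt[pl, on = "product_code", `:=`(.lo = i..lo, .hi = i..hi, .def = i..def)]
  v <- dt[[field]]
  dt[, `:=`(.plaus = !is.na(v) & (is.na(.lo) | v >= .lo) &
              (is.na(.hi) | v <= .hi))]
  pv <- ifelse(dt$.plaus, as.numeric(v), NA_real_)
  if (any(c("pop", "pat", "prev") %in% need)) dt[, .pv := pv]
  if ("pop" %in% need) {
    agg <- dt[, .(.pop = mean(.pv, na.rm = TRUE)), by = product_code]
    dt[agg, on = "product_code", .pop := i..pop]
    dt[is.nan(.pop), .pop := NA_real_]
  }
  if ("pat" %in% need) {
    agg <- dt[, .(.pat = mean(.pv, na.rm = TRUE)),
              by = .(patient_id, product_code)]
    dt[agg, on = c("patient_id", "product_code"), .pat := i..pat]
    dt[is.nan(.pat), .pat := NA_real_]
  }
  if ("prev" %in% need) {
    dt[, .row := .I]
    setorder(dt, patient_id, product_code, start_date, .row)
    gid <- rleidv(dt, cols = c("patient_id", "product_code"))
    dt[, .prev := .prev_in_group(.pv, gid)]
    setorder(dt, .row)
  }
  dt
}

.strip_helpers <- function(dt) {
  drop <- intersect(c(".lo", ".hi", ".def", ".plaus", ".pv", ".pop", ".pat",
                      ".prev", ".row"), names(dt))
  if (length(drop)) dt[, (drop) := NULL]
  dt
}

# Resolve implausible (non-missing, out-of-bounds) values of `field`.
# method: leave | missing | pop | pat | cap. Returns count list.
.apply_implausible <- function(dt, field, method, round_days = FALSE) {
  idx <- which(!is.na(dt[[field]]) & !dt$.plaus)
  counts <- list(modified = 0L, set_missing = 0L)
  if (method == "leave" || !length(idx)) return(counts)
  v <- as.numeric(dt[[field]])
  if (method == "missing") {
    v[idx] <- NA_real_
    counts$set_missing <- length(idx)
  } else if (method == "cap") {
    v[idx] <- pmin(pmax(v[idx], dt$.lo[idx]), dt$.hi[idx])
    counts$modified <- length(idx)
  } else {
    stat <- if (method == "pop") dt$.pop else dt$.pat
    repl <- ifelse(is.na(stat[idx]), dt$.def[idx], stat[idx])
    if (round_days) repl <- round_half_up(repl)
    v[idx] <- repl
    counts$modified <- sum(!is.na(repl))
    counts$set_missing <- sum(is.na(repl))
  }
  set(dt, j = field, value = v)
  counts
}

# Impute missing values of `field`.
# method: leave | pop | pat | carry | default. Returns count list.
.apply_missing <- function(dt, field, method, round_days = FALSE) {
  idx <- which(is.na(dt[[field]]))
  counts <- list(modified = 0L, set_missing = 0L)
  if (method == "leave" || !length(idx)) return(counts)
  repl <- switch(method,
    pop = ifelse(is.na(dt$.pop[idx]), dt$.def[idx], dt$.pop[idx]),
    pat = ifelse(is.na(dt$.pat[idx]), dt$.def[idx], dt$.pat[idx]),
    carry = dt$.prev[idx],
    default = dt$.def[idx],
    stop("unknown imputation method: ", method))
  if (round_days) repl <- round_half_up(repl)
  v <- as.numeric(dt[[field]])
  v[idx] <- repl
  set(dt, j = field, value = v)
  counts$modified <- sum(!is.na(repl))
  counts
}

.option_letter <- function(token, node) {
  if (option_node(token) != node)
    stop("option '", token, "' does not belong to node ", node)
  sub("^[0-9]+", "", option_base(token))
}

# Shared driver for the qty (nodes 1/2) and ndd (nodes 3/4) pairs.
.clean_value_pair <- function(records, imp_token, miss_token, plausibility,
                              ledger, field, lo, hi, def,
                              imp_node, miss_node, imp_map, miss_map) {
  records <- as_therapy(records)
  plausibility <- as_plausibility(plausibility)
  .warn_unknown_products(records, plausibility)
  imp_method <- imp_map[[.option_letter(imp_token, imp_node)]]
  miss_method <- miss_map[[.option_letter(miss_token, miss_node)]]
  n <- nrow(records)

  # each node freezes a snapshot of its own input: the implausibility node
  # sees the raw values, the missingness node sees that node's output
  dt <- .prep_field(records, plausibility, field, lo, hi, def,
                    need = intersect(imp_method, c("pop", "pat")))
  c1 <- .apply_implausible(dt, field, imp_method)
  ledger_add(ledger, as.character(imp_node), n,
             records_modified = c1$modified,
             records_set_missing = c1$set_missing)
  dt <- .strip_helpers(dt)

  dt <- .prep_field(dt, plausibility, field, lo, hi, def,
                    need = intersect(c(miss_method,
                                       if (miss_method == "carry") "prev"),
                                     c("pop", "pat", "prev")))
  c2 <- .apply_missing(dt, field, miss_method)
  ledger_add(ledger, as.character(miss_node), n,
             records_modified = c2$modified)

  .strip_helpers(dt)
  dt[]
}

#' Clean the prescription quantity field (nodes 1 and 2)
#'
#' Node 1 resolves implausible `qty` (outside the product's
#' `[qty_min, qty_max]`): 1a leave as-is, 1b set missing, 1c product
#' population mean of plausible values, 1d patient mean of plausible values
#' for that product, 1e cap at the nearest bound. Node 2 then resolves
#' missing `qty`: 2a leave missing, 2b population mean, 2c patient mean,
#' 2d carry the patient's previous plausible value forward, 2e product
#' `default_qty`.
#'
#' @param records therapy table (see [as_therapy()])
#' @param node1_option,node2_option option tokens, e.g. `"1b"`, `"2a"`
#' @param plausibility plausibility table (see [as_plausibility()])
#' @param ledger optional [new_ledger()] to receive per-node counts
#' @return the cleaned therapy `data.table` (same number of rows)
#' @examples
#' pl <- data.frame(product_code = "P1", qty_min = 1, qty_max = 500,
#'                  ndd_min = 0.5, ndd_max = 12, dur_min = 1, dur_max = 186,
#'                  default_qty = 56, default_ndd = 2,
#'                  default_duration_days = 28)
#' rx <- data.frame(patient_id = 1, product_code = "P1", start_date = 0,
#'                  qty = 5000, ndd = 2, numdays = NA, dose_duration = NA)
#' clean_quantity(rx, "1e", "2a", pl)$qty   # capped at 500
#' @export
clean_quantity <- function(records, node1_option = "1a", node2_option = "2a",
                           plausibility, ledger = NULL) {
  .clean_value_pair(records, node1_option, node2_option, plausibility, ledger,
    field = "qty", lo = "qty_min", hi = "qty_max", def = "default_qty",
    imp_node = 1L, miss_node = 2L,
    imp_map = c(a = "leave", b = "missing", c = "pop", d = "pat", e = "cap"),
    miss_map = c(a = "leave", b = "pop", c = "pat", d = "carry",
                 e = "default"))
}

#' Clean the numeric daily dose field (nodes 3 and 4)
#'
#' Node 3 mirrors node 1 for `ndd` (3a leave, 3b set missing, 3c population
#' mean, 3d patient mean, 3e cap). Node 4 resolves missing `ndd`: 4a leave
#' missing, 4b patient mean, 4c population mean for that product code,
#' 4d carry forward, 4e product `default_ndd`.
#'
#' @inheritParams clean_quantity
#' @param node3_option,node4_option option tokens, e.g. `"3b"`, `"4b"`
#' @return the cleaned therapy `data.table`
#' @export
clean_daily_dose <- function(records, node3_option = "3a",
                             node4_option = "4a", plausibility,
                             ledger = NULL) {
  .clean_value_pair(records, node3_option, node4_option, plausibility, ledger,
    field = "ndd", lo = "ndd_min", hi = "ndd_max", def = "default_ndd",
    imp_node = 3L, miss_node = 4L,
    imp_map = c(a = "leave", b = "missing", c = "pop", d = "pat", e = "cap"),
    miss_map = c(a = "leave", b = "pat", c = "pop", d = "carry",
                 e = "default"))
}

#' Clean the duration fields (node 5)
#'
#' Node 5 resolves implausible `numdays` and `dose_duration` (outside the
#' product's `[dur_min, dur_max]`), applied to both fields independently:
#' 5a leave as-is, 5b set missing, 5c cap at the nearest bound, 5d population
#' mean plausible duration (per field and product), 5e patient mean plausible
#' duration. Imputed durations are rounded half-up to whole days. Node 5
#' handles implausible values only; records left without any usable duration
#' are the business of Step B.
#'
#' @inheritParams clean_quantity
#' @param node5_option option token, e.g. `"5b"`
#' @return the cleaned therapy `data.table`
#' @export
clean_duration_fields <- function(records, node5_option = "5a", plausibility,
                                  ledger = NULL) {
  records <- as_therapy(records)
  plausibility <- as_plausibility(plausibility)
  .warn_unknown_products(records, plausibility)
  imp_map <- c(a = "leave", b = "missing", c = "cap", d = "pop", e = "pat")
  method <- imp_map[[.option_letter(node5_option, 5L)]]
  n <- nrow(records)
  modified <- set_missing <- logical(n)
  out <- records
  for (field in c("numdays", "dose_duration")) {
    dt <- .prep_field(out, plausibility, field, "dur_min", "dur_max",
                      "default_duration_days",
                      need = intersect(method, c("pop", "pat")))
    before <- dt[[field]]
    .apply_implausible(dt, field, method, round_days = TRUE)
    after <- dt[[field]]
    changed <- which(!is.na(before) & (is.na(after) | after != before))
    set_missing[changed[is.na(after[changed])]] <- TRUE
    modified[changed[!is.na(after[changed])]] <- TRUE
    out <- .strip_helpers(dt)
  }
  ledger_add(ledger, "5", n, records_modified = sum(modified),
             records_set_missing = sum(set_missing))
  out[]
}
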