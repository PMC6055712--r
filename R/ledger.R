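#' Audit ledger of per-node record counts
#'
#' Every preparation stage records how many records (or episodes, in Step C)
#' entered the node, how many were modified, set missing, or removed, and how
#' many left. Removed rows — whether discarded for cause (node 7 missing stop
#' dates, node 9e) or absorbed by a collapse/merge (nodes 8, 9c/9d, 10) — are
#' counted in `records_dropped`, so conservation
#' `records_out = records_in - records_dropped` holds at every node and
#' consecutive nodes chain (`records_out` of node k equals `records_in` of
#' node k+1 within the record stages and within the episode stages).
#'
#' The ledger is an environment so that pipeline stages can append to it in
#' place; convert with [ledger_table()] (or `as.data.frame()`).
#'
#' @return `new_ledger()` returns an empty `audit_ledger`.
#' @examples
#' led <- new_ledger()
#' ledger_add(led, "1", records_in = 10, records_modified = 2)
#' ledger_table(led)
#' @export
new_ledger <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  class(env) <- "audit_ledger"
  env
}

#' @rdname new_ledger
#' @param ledger an `audit_ledger` (or `NULL`, in which case the call is a
#'   no-op so pipeline stages can run unaudited)
#' @param node node label: `"1"` to `"10"`, or `"clip"` for the final
#'   clipping to follow-up
#' @param records_in,records_modified,records_set_missing,records_dropped
#'   counts for the node
#' @export
ledger_add <- function(ledger, node, records_in, records_modified = 0L,
                       records_set_missing = 0L, records_dropped = 0L) {
  if (is.null(ledger)) return(invisible(NULL))
  stopifnot(inherits(ledger, "audit_ledger"))
  row <- data.table(
    node = as.character(node),
    records_in = as.integer(records_in),
    records_modified = as.integer(records_modified),
    records_set_missing = as.integer(records_set_missing),
    records_dropped = as.integer(records_dropped),
    records_out = as.integer(records_in) - as.integer(records_dropped)
  )
  ledger$rows[[length(ledger$rows) + 1L]] <- row
  invisible(ledger)
}

#' @rdname new_ledger
#' @export
ledger_table <- function(ledger) {
  if (is.null(ledger) || !length(ledger$rows)) {
    return(data.table(node = character(), records_in = integer(),
                      records_modified = integer(),
                      records_set_missing = integer(),
                      records_dropped = integer(),
                      records_out = integer()))
  }
  rbindlist(ledger$rows)
}

#' @export
as.data.frame.audit_ledger <- function(x, ...) {
  as.data.frame(ledger_table(x))
}

#' @export
print.audit_ledger <- function(x, ...) {
  cat("Audit ledger:\n")
  print(ledger_table(x))
  invisible(x)
}
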