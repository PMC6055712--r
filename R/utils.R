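#' @import data.table
#' @importFrom stats median quantile rexp rpois runif setNames coef
#' @importFrom survival coxph Surv
#' @importFrom graphics boxplot par
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "patient_id", "product_code", "start_date",
  "stop_date", "qty", "ndd", "numdays", "dose_duration", "drug_class",
  "start", "stop", "entry", "exit", "event_date", "state", "event",
  "exposed", "duration", "..keep"
))

.datatable.aware <- TRUE

#' Round half away from zero to whole days
#'
#' Day-granular convention used throughout: fractional durations and mean
#' dates are rounded half-up, so the mean of two days with an odd difference
#' lands on the later day.
#'
#' @param x numeric vector
#' @return numeric vector of whole numbers
#' @examples
#' round_half_up(c(0.5, 1.5, 29.5, 18.67))
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
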