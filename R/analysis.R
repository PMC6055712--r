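#' Downstream survival analysis of prepared exposure timelines
#'
#' The prepared episodes define a time-varying binary (or multi-class)
#' exposure state. Follow-up is split into counting-process rows alternating
#' between states, the outcome event is assigned to the interval ending at
#' the event date, and the exposure contrast is fitted by Cox proportional
#' hazards with no covariates. Day-granular data guarantee tied event times,
#' so the Breslow tie approximation is used throughout; confidence intervals
#' are Wald intervals on the log scale (log HR +/- 1.96 SE).
#'
#' @name analysis
NULL

#' Split follow-up into exposure person-time rows
#'
#' @param timeline clipped exposure episodes (`patient_id`, `drug_class`,
#'   `start`, `stop`) as produced by [run_pathway()] with a follow-up table
#' @param followup table with `patient_id`, `entry`, `exit` and optionally
#'   `event_date` (NA for censored patients)
#' @param events optional table (`patient_id`, `event_date`) overriding the
#'   event dates in `followup`
#' @return counting-process rows: `patient_id`, `start`, `stop`, `state`
#'   (the episode's drug class, or `"unexposed"`), `event` (0/1; at most one
#'   row per patient, the row ending at the event date). Follow-up is
#'   censored at the event; rows after it are not emitted. An event dated
#'   outside `(entry, exit]` is ignored with a warning. For every patient
#'   the rows partition `[entry, min(event, exit))` exactly.
#' @examples
#' tl <- data.frame(patient_id = 1, drug_class = "drug",
#'                  start = 10, stop = 40)
#' fu <- data.frame(patient_id = 1, entry = 0, exit = 100, event_date = 25)
#' split_person_time(tl, fu)
#' @export
split_person_time <- function(timeline, followup, events = NULL) {
  fu <- as.data.table(followup)
  stopifnot(all(c("patient_id", "entry", "exit") %in% names(fu)))
  fu <- fu[, .(patient_id, entry = as.integer(entry),
               exit = as.integer(exit),
               event_date = if ("event_date" %in% names(fu))
                 as.integer(event_date) else NA_integer_)]
  if (!is.null(events)) {
    ev <- as.data.table(events)
    stopifnot(all(c("patient_id", "event_date") %in% names(ev)))
    fu[, event_date := NA_integer_]
    fu[ev, on = "patient_id", event_date := as.integer(i.event_date)]
  }
  if (any(fu$exit <= fu$entry)) stop("follow-up requires exit > entry")
  bad <- !is.na(fu$event_date) &
    (fu$event_date <= fu$entry | fu$event_date > fu$exit)
  if (any(bad)) {
    warning(sum(bad), " event(s) outside follow-up ignored", call. = FALSE)
    fu[bad, event_date := NA_integer_]
  }
  fu[, exit_eff := ifelse(is.na(event_date), exit, event_date)]

  ep <- as.data.table(timeline)
  if (nrow(ep)) {
    ep <- fu[, .(patient_id, entry, exit_eff)][ep, on = "patient_id"]
    ep <- ep[!is.na(entry)]
    ep[, `:=`(start = pmax(start, entry), stop = pmin(stop, exit_eff))]
    ep <- ep[stop > start]
    setorder(ep, patient_id, start)
    # overlapping episodes across classes are not modelled; truncate with a
    # warning so every day has a single state
    ep[, prev_stop := shift(cummax(stop)), by = patient_id]
    if (any(!is.na(ep$prev_stop) & ep$start < ep$prev_stop)) {
      warning("overlapping episodes across drug classes truncated",
              call. = FALSE)
      ep[!is.na(prev_stop), start := pmax(start, prev_stop)]
      ep <- ep[stop > start]
    }
    ep[, prev_stop := NULL]
  }

  exp_rows <- if (nrow(ep)) ep[, .(patient_id, start, stop,
                                   state = as.character(drug_class))]
  else data.table(patient_id = fu$patient_id[0], start = integer(),
                  stop = integer(), state = character())

  # unexposed complement: gaps between episodes plus head and tail
  if (nrow(ep)) {
    gaps <- ep[, {
      s <- c(entry[1L], stop)
      e <- c(start, exit_eff[1L])
      .(start = s, stop = e)
    }, by = patient_id]
    gaps <- gaps[stop > start]
  } else {
    gaps <- data.table(patient_id = integer(0), start = integer(0),
                       stop = integer(0))
  }
  no_ep <- fu[!patient_id %in% unique(ep$patient_id) & exit_eff > entry,
              .(patient_id, start = entry, stop = exit_eff)]
  unexp_rows <- rbind(gaps, no_ep)
  unexp_rows[, state := "unexposed"]

  rows <- rbind(exp_rows, unexp_rows)
  setorder(rows, patient_id, start)
  rows[fu, on = "patient_id", `:=`(event_date = i.event_date)]
  rows[, event := as.integer(!is.na(event_date) & stop == event_date)]
  rows[, event_date := NULL]
  rows[]
}

#' Fit the time-varying exposure contrast (Cox model)
#'
#' Fits a proportional-hazards model on counting-process rows with the
#' exposure state as the only covariate (no adjustment), Breslow ties, and
#' returns the log hazard ratio of `contrast` vs `referent` with its
#' model-based SE and 95% Wald CI. Non-estimable situations — no events, a
#' single represented state, zero person-time in a contrast level, a failed
#' fit or a monotone likelihood (infinite coefficient) — yield
#' `estimable = FALSE` rather than an error.
#'
#' @param rows person-time rows from [split_person_time()]
#' @param referent state label used as the referent group
#' @param contrast state label contrasted against the referent; default:
#'   the first non-referent state present
#' @return one-row `data.table`: `log_hr`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `n_events`, `estimable`
#' @export
fit_exposure_model <- function(rows, referent = "unexposed",
                               contrast = NULL) {
  rows <- as.data.table(rows)
  not_est <- data.table(log_hr = NA_real_, se = NA_real_, hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_events = sum(rows$event %||% 0L),
                        estimable = FALSE)
  if (nrow(rows) == 0L || sum(rows$event) < 1L) return(not_est)
  lev <- unique(rows$state)
  contrast <- contrast %||% setdiff(lev, referent)[1L]
  if (is.na(contrast) || !all(c(referent, contrast) %in% lev))
    return(not_est)
  pt <- rows[, .(pt = sum(stop - start)), by = state]
  if (any(pt[state %in% c(referent, contrast), pt] <= 0)) return(not_est)
  rows[, state := factor(state, levels = c(referent, setdiff(lev, referent)))]
  infinite_coef <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(survival::Surv(start, stop, event) ~ state,
                      data = rows, ties = "breslow"),
      error = function(e) NULL),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w)))
        infinite_coef <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || infinite_coef) return(not_est)
  cname <- paste0("state", contrast)
  co <- stats::coef(fit)
  if (!cname %in% names(co)) return(not_est)
  b <- unname(co[cname])
  se <- sqrt(diag(fit$var))[match(cname, names(co))]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15) return(not_est)
  data.table(log_hr = b, se = se, hr = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             n_events = sum(rows$event), estimable = TRUE)
}

#' Prepare one pathway and fit its exposure contrast
#'
#' Runs [run_pathway()], splits person-time, fits the Cox contrast, and
#' returns a one-row pathway result. `n_records_dropped` counts records
#' discarded for cause (node 7 unresolved stop dates, node 9e overlaps).
#'
#' @inheritParams run_pathway
#' @param followup follow-up table with `entry`, `exit`, `event_date`
#' @param events optional separate events table
#' @param referent,contrast passed to [fit_exposure_model()]
#' @return one-row `data.table` with `pathway`, the fit columns, and
#'   `n_records_dropped`
#' @export
run_pathway_analysis <- function(raw, spec, plausibility, followup,
                                 events = NULL, referent = "unexposed",
                                 contrast = NULL,
                                 registry = default_registry()) {
  if (!inherits(spec, "pathway_spec")) spec <- parse_pathway(spec)
  prep <- run_pathway(raw, spec, plausibility, followup, registry)
  rows <- split_person_time(prep$episodes, followup, events)
  fit <- fit_exposure_model(rows, referent, contrast)
  dropped <- prep$ledger[node %in% c("7", "9"), sum(records_dropped)]
  cbind(data.table(pathway = format_pathway(spec)), fit,
        data.table(n_records_dropped = as.integer(dropped)))
}

#' Two-stage sensitivity experiment over preparation pathways
#'
#' Stage 1 draws `k_random` pathways uniformly from the registry and
#' prepares + fits each. Stage 2 runs the primary pathway and every
#' one-at-a-time variant of it. Per-pathway failures are recorded as
#' non-estimable rows; the experiment never aborts.
#'
#' @inheritParams run_pathway_analysis
#' @param registry a `decision_registry`
#' @param primary the primary `pathway_spec`
#' @param k_random number of stage-1 random pathways
#' @param seed RNG seed for the stage-1 draw
#' @return `data.table` of pathway results with columns `stage` (`"random"`,
#'   `"primary"`, `"variant"`), `varied_node` (NA except for variants), the
#'   pathway token string, fit columns and drop counts; class
#'   `pathway_results`
#' @export
sensitivity_experiment <- function(raw, registry = default_registry(),
                                   primary = default_primary_pathway(),
                                   k_random = 50L, seed = 1L,
                                   plausibility, followup, events = NULL,
                                   referent = "unexposed", contrast = NULL) {
  run_one <- function(spec, stage, varied_node = NA_integer_) {
    res <- tryCatch(
      suppressWarnings(
        run_pathway_analysis(raw, spec, plausibility, followup, events,
                             referent, contrast, registry)),
      error = function(e) {
        data.table(pathway = format_pathway(spec), log_hr = NA_real_,
                   se = NA_real_, hr = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, n_events = NA_integer_,
                   estimable = FALSE, n_records_dropped = NA_integer_)
      })
    cbind(data.table(stage = stage, varied_node = varied_node), res)
  }
  stage1 <- lapply(sample_random_pathways(registry, k_random, seed),
                   run_one, stage = "random")
  stage2 <- list(run_one(primary, "primary"))
  for (v in one_at_a_time_variants(primary, registry)) {
    stage2[[length(stage2) + 1L]] <-
      run_one(v, "variant", attr(v, "varied_node"))
  }
  out <- rbindlist(c(stage1, stage2))
  setattr(out, "class", c("pathway_results", class(out)))
  out[]
}

#' Summarise a set of pathway results
#'
#' Median HR and SE, the HR interquartile range, Tukey outliers (beyond
#' 1.5 IQR from the quartiles) and, optionally, pathways beyond fixed
#' absolute HR thresholds; computed over estimable results only.
#'
#' @param results a `pathway_results` table (or any table with `pathway`,
#'   `hr`, `se`, `estimable`)
#' @param hr_low,hr_high optional absolute HR thresholds to flag
#' @return a `pathway_summary` list: `n`, `n_nonestimable`, `median_hr`,
#'   `median_se`, `iqr_hr`, `outliers` (data.table of flagged pathways)
#' @export
summarize_results <- function(results, hr_low = NULL, hr_high = NULL) {
  res <- as.data.table(results)
  est <- res[estimable == TRUE]
  if (nrow(est) == 0L) stop("no estimable pathway results to summarise")
  q <- quantile(est$hr, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  flag <- est$hr < lo | est$hr > hi
  if (!is.null(hr_low)) flag <- flag | est$hr < hr_low
  if (!is.null(hr_high)) flag <- flag | est$hr > hr_high
  out <- list(
    n = nrow(res), n_nonestimable = nrow(res) - nrow(est),
    median_hr = median(est$hr), median_se = median(est$se),
    iqr_hr = iqr,
    outliers = est[flag, .(pathway, hr, se)])
  class(out) <- "pathway_summary"
  out
}

#' @export
print.pathway_summary <- function(x, ...) {
  cat(sprintf(
    "Pathway results: %d (non-estimable: %d)\n median HR %.3f, median SE %.3f, IQR(HR) %.3f\n",
    x$n, x$n_nonestimable, x$median_hr, x$median_se, x$iqr_hr))
  if (nrow(x$outliers)) {
    cat(" outlying pathways:\n")
    print(x$outliers)
  } else cat(" no outlying pathways\n")
  invisible(x)
}

#' @export
plot.pathway_results <- function(x, ...) {
  est <- as.data.table(x)[estimable == TRUE]
  if (nrow(est) == 0L) stop("no estimable results to plot")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(est$hr, ylab = "Hazard ratio", main = "HR", ...)
  graphics::boxplot(est$se, ylab = "Standard error (log HR)", main = "SE",
                    ...)
  invisible(x)
}
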