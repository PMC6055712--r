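#' Synthetic cohort generator
#'
#' Generates primary-care-like raw therapy, follow-up and ground-truth
#' tables so that every preparation stage and the downstream survival
#' contrast can be tested without access to any real EHR extract. Two
#' prescribing regimes are emulated: `"continuous"` (long-term repeat
#' prescribing, as for oral hypoglycaemics — sparse field missingness apart
#' from the duration fields: 12.5% missing `ndd`, 97.2% missing `numdays`,
#' 99.9% missing `dose_duration`) and `"intermittent"` (short courses with
#' long breaks, as for oral glucocorticoids — 50% missing `ndd`, 97% missing
#' `numdays`, 99.2% missing `dose_duration`).
#'
#' Before corruption every record's three duration sources agree exactly
#' with the ground truth: `numdays` and `dose_duration` equal the true
#' duration and `qty = duration x ndd`. Corruption then masks each field
#' independently at the configured missingness rates and replaces a fraction
#' of the surviving values with out-of-bounds ones. Outcome event times are
#' drawn from an exponential model whose hazard is
#' `baseline_hazard x exp(log_hr)` during true exposure.
#'
#' Product codes are pack-level granular (as in primary-care product
#' dictionaries, where each brand/strength/pack is a distinct code): each
#' prescription draws its code uniformly from the class's
#' `n_products` codes, so patient-by-product donor pools are small.
#'
#' @param n_patients cohort size
#' @param regime `"continuous"` or `"intermittent"`
#' @param seed integer RNG seed driving all randomness
#' @param followup_range min/max follow-up length in days (uniform)
#' @param n_products product codes in the drug class
#' @param ndd_levels possible units-per-day values, one assigned per product
#' @param rx_durations,rx_duration_probs prescription duration menu (days)
#' @param refill_gap_mean mean Poisson gap between consecutive refills (days)
#' @param treated_frac_range fraction of post-initiation follow-up covered
#'   by therapy (continuous regime)
#' @param courses_range number of treatment courses (intermittent regime)
#' @param course_rx_range refills per course (intermittent regime)
#' @param course_gap_range gap between courses in days (intermittent regime)
#' @param overlap_prob probability a refill is issued early, overlapping its
#'   predecessor by 1-7 days
#' @param duplicate_prob probability a record is duplicated on the same day
#' @param miss_qty,miss_ndd,miss_numdays,miss_dose_duration field-level
#'   missingness rates (regime defaults above)
#' @param contamination_rate fraction of surviving non-missing values
#'   replaced by implausible ones
#' @param log_hr true log hazard ratio of exposure
#' @param baseline_hazard baseline hazard, events per person-day
#' @return `generator_config()` returns a validated config object.
#' @examples
#' cfg <- generator_config(n_patients = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' names(cohort)
#' @export
generator_config <- function(n_patients = 2000,
                             regime = c("continuous", "intermittent"),
                             seed = 1L,
                             followup_range = c(365L, 1095L),
                             n_products = 12L,
                             ndd_levels = c(1, 2, 3, 4),
                             rx_durations = NULL,
                             rx_duration_probs = NULL,
                             refill_gap_mean = NULL,
                             treated_frac_range = c(0.4, 0.9),
                             courses_range = c(1L, 4L),
                             course_rx_range = c(1L, 4L),
                             course_gap_range = c(60L, 180L),
                             overlap_prob = 0.10,
                             duplicate_prob = 0.02,
                             miss_qty = 0.01,
                             miss_ndd = NULL,
                             miss_numdays = NULL,
                             miss_dose_duration = NULL,
                             contamination_rate = 0.02,
                             log_hr = log(2),
                             baseline_hazard = 2e-4) {
  regime <- match.arg(regime)
  if (regime == "continuous") {
    rx_durations <- rx_durations %||% c(28L, 56L)
    rx_duration_probs <- rx_duration_probs %||% c(0.8, 0.2)
    refill_gap_mean <- refill_gap_mean %||% 2
    miss_ndd <- miss_ndd %||% 0.125
    miss_numdays <- miss_numdays %||% 0.972
    miss_dose_duration <- miss_dose_duration %||% 0.999
  } else {
    rx_durations <- rx_durations %||% c(7L, 14L, 28L)
    rx_duration_probs <- rx_duration_probs %||% c(0.3, 0.4, 0.3)
    refill_gap_mean <- refill_gap_mean %||% 5
    miss_ndd <- miss_ndd %||% 0.50
    miss_numdays <- miss_numdays %||% 0.97
    miss_dose_duration <- miss_dose_duration %||% 0.992
  }
  cfg <- list(
    n_patients = as.integer(n_patients), regime = regime,
    seed = as.integer(seed), followup_range = followup_range,
    n_products = as.integer(n_products), ndd_levels = ndd_levels,
    rx_durations = rx_durations, rx_duration_probs = rx_duration_probs,
    refill_gap_mean = refill_gap_mean,
    treated_frac_range = treated_frac_range,
    courses_range = courses_range, course_rx_range = course_rx_range,
    course_gap_range = course_gap_range,
    overlap_prob = overlap_prob, duplicate_prob = duplicate_prob,
    miss_qty = miss_qty, miss_ndd = miss_ndd, miss_numdays = miss_numdays,
    miss_dose_duration = miss_dose_duration,
    contamination_rate = contamination_rate,
    log_hr = log_hr, baseline_hazard = baseline_hazard)
  rates <- c(cfg$overlap_prob, cfg$duplicate_prob, cfg$miss_qty, cfg$miss_ndd,
             cfg$miss_numdays, cfg$miss_dose_duration, cfg$contamination_rate)
  stopifnot(cfg$n_patients >= 1L, all(rates >= 0 & rates <= 1),
            cfg$baseline_hazard > 0,
            length(cfg$rx_durations) == length(cfg$rx_duration_probs))
  class(cfg) <- "generator_config"
  cfg
}

# merge touching/overlapping half-open intervals to disjoint sorted episodes
.merge_union <- function(start, stop) {
  o <- order(start, stop)
  start <- start[o]; stop <- stop[o]
  grp <- cumsum(c(TRUE, start[-1L] > cummax(stop)[-length(stop)]))
  list(start = as.integer(tapply(start, grp, min)),
       stop = as.integer(tapply(stop, grp, max)))
}

#' @rdname generator_config
#' @param config a `generator_config`
#' @return `generate_cohort()` returns a list with `therapy` (raw corrupted
#'   prescription records), `followup` (`patient_id`, `entry`, `exit`,
#'   `event_date` — NA when no event), `truth` (ground-truth exposure
#'   episodes, merged, disjoint and sorted), `plausibility` (the per-product
#'   bounds table consistent with the generating values), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$seed, {
    products <- data.table(
      product_code = sprintf("P%02d", seq_len(cfg$n_products)),
      drug_class = "drug",
      ndd_true = sample(cfg$ndd_levels, cfg$n_products, replace = TRUE))

    L <- as.integer(round(runif(cfg$n_patients, cfg$followup_range[1],
                                cfg$followup_range[2])))
    followup <- data.table(patient_id = seq_len(cfg$n_patients),
                           entry = 0L, exit = L)

    rx_list <- vector("list", cfg$n_patients)
    truth_list <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      t0 <- floor(runif(1, 0, L[i] / 2))
      starts <- integer(0); durs <- integer(0)
      emit_course <- function(from, n_rx_max, t_end) {
        cur <- from
        k <- 0L
        while (cur < t_end && (is.na(n_rx_max) || k < n_rx_max)) {
          d <- sample(cfg$rx_durations, 1L, prob = cfg$rx_duration_probs)
          starts <<- c(starts, as.integer(cur))
          durs <<- c(durs, as.integer(d))
          k <- k + 1L
          gap <- rpois(1L, cfg$refill_gap_mean)
          if (runif(1) < cfg$overlap_prob) gap <- -sample(1:7, 1L)
          cur <- max(cur + d + gap, cur + 1L)
        }
      }
      if (cfg$regime == "continuous") {
        treated <- floor(runif(1, cfg$treated_frac_range[1],
                               cfg$treated_frac_range[2]) * (L[i] - t0))
        emit_course(t0, NA, t0 + max(treated, 1))
      } else {
        n_courses <- sample(cfg$courses_range[1]:cfg$courses_range[2], 1L)
        cur <- t0
        for (k in seq_len(n_courses)) {
          n_rx <- sample(cfg$course_rx_range[1]:cfg$course_rx_range[2], 1L)
          before <- length(starts)
          emit_course(cur, n_rx, L[i])
          added <- length(starts) - before
          if (added == 0L) break
          last_stop <- max(starts[(before + 1L):length(starts)] +
                             durs[(before + 1L):length(starts)])
          cur <- last_stop + round(runif(1, cfg$course_gap_range[1],
                                         cfg$course_gap_range[2]))
          if (cur >= L[i]) break
        }
      }
      if (!length(starts)) next
      dup <- runif(length(starts)) < cfg$duplicate_prob
      if (any(dup)) {
        starts <- c(starts, starts[dup])
        durs <- c(durs, durs[dup])
      }
      rx_list[[i]] <- data.table(patient_id = i, start_date = starts,
                                 true_duration = durs)
      tu <- .merge_union(starts, starts + durs)
      truth_list[[i]] <- data.table(patient_id = i, drug_class = "drug",
                                    start = tu$start, stop = tu$stop)
    }
    rx <- rbindlist(rx_list)
    truth <- rbindlist(truth_list)
    if (is.null(rx) || nrow(rx) == 0L)
      stop("generator produced no prescriptions; enlarge the cohort")
    setorder(rx, patient_id, start_date)
    setorder(truth, patient_id, start)

    # consistent raw fields, then corruption
    rx[, product_code := products$product_code[
      sample.int(cfg$n_products, .N, replace = TRUE)]]
    rx[products, on = "product_code", ndd := i.ndd_true]
    rx[, `:=`(qty = true_duration * ndd,
              numdays = as.numeric(true_duration),
              dose_duration = as.numeric(true_duration))]
    mask <- function(v, rate) {
      v[runif(length(v)) < rate] <- NA_real_
      v
    }
    rx[, `:=`(qty = mask(qty, cfg$miss_qty),
              ndd = mask(ndd, cfg$miss_ndd),
              numdays = mask(numdays, cfg$miss_numdays),
              dose_duration = mask(dose_duration, cfg$miss_dose_duration))]
    contaminate <- function(v, bad_values) {
      ok <- which(!is.na(v))
      hit <- ok[runif(length(ok)) < cfg$contamination_rate]
      v[hit] <- sample(bad_values, length(hit), replace = TRUE)
      v
    }
    if (cfg$contamination_rate > 0) {
      rx[, `:=`(qty = contaminate(qty, c(5000, 9999)),
                ndd = contaminate(ndd, c(0, 99)),
                numdays = contaminate(numdays, c(999, 1500)),
                dose_duration = contaminate(dose_duration, c(999, 1500)))]
    }
    therapy <- rx[, .(patient_id, product_code, start_date, qty, ndd,
                      numdays, dose_duration)]

    plausibility <- products[, .(
      product_code, drug_class,
      qty_min = 1, qty_max = 500, ndd_min = 0.5, ndd_max = 12,
      dur_min = 1, dur_max = 186,
      default_qty = 56, default_ndd = 2, default_duration_days = 28)]

    # outcome: piecewise-constant hazard over the true exposure timeline
    followup[, event_date := NA_integer_]
    haz0 <- cfg$baseline_hazard
    haz1 <- cfg$baseline_hazard * exp(cfg$log_hr)
    truth_by_pat <- split(truth, by = "patient_id", keep.by = TRUE)
    target <- rexp(cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      tb <- truth_by_pat[[as.character(i)]]
      bounds <- c(0L, L[i])
      if (!is.null(tb)) {
        tb <- tb[start < L[i]]
        s <- pmax(tb$start, 0L); e <- pmin(tb$stop, L[i])
        keep <- e > s
        bounds <- sort(unique(c(0L, L[i], s[keep], e[keep])))
      }
      seg_s <- head(bounds, -1L); seg_e <- tail(bounds, -1L)
      seg_exposed <- rep(FALSE, length(seg_s))
      if (!is.null(tb) && nrow(tb)) {
        for (j in seq_len(nrow(tb)))
          seg_exposed <- seg_exposed | (seg_s >= tb$start[j] &
                                          seg_e <= tb$stop[j])
      }
      haz <- ifelse(seg_exposed, haz1, haz0)
      cum <- cumsum(haz * (seg_e - seg_s))
      hit <- which(cum >= target[i])
      if (length(hit)) {
        j <- hit[1L]
        prev <- if (j == 1L) 0 else cum[j - 1L]
        t_event <- seg_s[j] + (target[i] - prev) / haz[j]
        followup[i, event_date := as.integer(min(ceiling(t_event), L[i]))]
      }
    }
    setattr(truth, "patients", seq_len(cfg$n_patients))
    list(therapy = therapy, followup = followup[], truth = truth,
         plausibility = plausibility, config = cfg)
  })
}

#' Ground-truth exposure episodes for one patient
#'
#' @param truth the `truth` table from [generate_cohort()]
#' @param patient_id a patient present in the cohort
#' @return that patient's disjoint, sorted ground-truth episodes (possibly
#'   zero rows for a patient with no prescriptions)
#' @export
truth_exposure <- function(truth, patient_id) {
  tt <- as.data.table(truth)
  known <- attr(truth, "patients") %||% unique(tt$patient_id)
  if (!patient_id %in% known)
    stop("unknown patient: ", patient_id)
  pid <- patient_id
  out <- tt[patient_id == pid]
  setorder(out, start)
  out[]
}
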