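test_that("person-time splitting produces the documented rows", {
  tl <- episode_rows(10, 40)
  fu <- data.table(patient_id = 1L, entry = 0L, exit = 100L,
                   event_date = NA_integer_)
  rows <- split_person_time(tl, fu)
  expect_equal(rows[, .(start, stop, state, event)],
               data.table(start = c(0L, 10L, 40L), stop = c(10L, 40L, 100L),
                          state = c("unexposed", "drug", "unexposed"),
                          event = 0L))
  # event at day 25 censors follow-up and lands on the exposed row
  fu$event_date <- 25L
  rows <- split_person_time(tl, fu)
  expect_equal(rows[, .(start, stop, state, event)],
               data.table(start = c(0L, 10L), stop = c(10L, 25L),
                          state = c("unexposed", "drug"),
                          event = c(0L, 1L)))
  # an events table overrides follow-up event dates
  rows <- split_person_time(tl, fu,
                            events = data.table(patient_id = 1L,
                                                event_date = 50L))
  expect_equal(rows[nrow(rows), .(stop, state, event)],
               data.table(stop = 50L, state = "unexposed", event = 1L))
  # events outside follow-up are ignored with a warning
  fu$event_date <- 200L
  expect_warning(rows <- split_person_time(tl, fu), "outside follow-up")
  expect_equal(sum(rows$event), 0L)
  # a patient with no episodes is one unexposed row
  rows <- split_person_time(episode_rows(integer(0), integer(0)),
                            data.table(patient_id = 2L, entry = 5L,
                                       exit = 50L))
  expect_equal(rows[, .(start, stop, state)],
               data.table(start = 5L, stop = 50L, state = "unexposed"))
})

test_that("person-time is conserved over random timelines", {
  set.seed(61)
  for (rep in 1:25) {
    n_pat <- 8L
    fu <- data.table(patient_id = 1:n_pat, entry = 0L,
                     exit = sample(50:200, n_pat, TRUE))
    fu[, event_date := ifelse(runif(n_pat) < 0.4,
                              pmin(exit, sample(1:200, n_pat, TRUE)),
                              NA_integer_)]
    fu[!is.na(event_date) & event_date <= entry, event_date := NA_integer_]
    eps <- rbindlist(lapply(1:n_pat, function(p) {
      e <- random_episodes(sample(1:4, 1), max_start = 150)
      out <- resolve_overlaps(episode_rows(e$start, e$stop, patient_id = p),
                              "9c")
    }))
    tl <- build_exposure_timeline(eps, fu)
    rows <- suppressWarnings(split_person_time(tl, fu))
    got <- rows[, .(pt = sum(stop - start)), by = patient_id]
    fu[, want := pmin(ifelse(is.na(event_date), exit, event_date), exit) -
         entry]
    merged <- got[fu, on = "patient_id"]
    expect_equal(merged$pt, merged$want)
    expect_true(all(rows$stop > rows$start))
    expect_true(all(rows[, sum(event), by = patient_id]$V1 <= 1L))
  }
})

test_that("the Cox fit matches the closed-form exponential rate ratio", {
  # two-state piecewise-exponential world, constant hazards; the Cox
  # partial-likelihood estimate must approach log((d1/T1)/(d0/T0))
  set.seed(71)
  n <- 1500
  half <- rep(c(TRUE, FALSE), length.out = n)
  h <- ifelse(half, 0.004, 0.002)  # true HR 2 between groups
  t_event <- rexp(n, rate = h)
  exit <- pmin(ceiling(t_event), 365L)
  event <- as.integer(ceiling(t_event) <= 365L)
  rows <- data.table(patient_id = 1:n, start = 0L, stop = exit,
                     state = ifelse(half, "drug", "unexposed"),
                     event = event)
  rows <- rows[stop > start]
  fit <- fit_exposure_model(rows)
  expect_true(fit$estimable)
  d1 <- rows[state == "drug", sum(event)]
  t1 <- rows[state == "drug", sum(stop - start)]
  d0 <- rows[state == "unexposed", sum(event)]
  t0 <- rows[state == "unexposed", sum(stop - start)]
  closed <- log((d1 / t1) / (d0 / t0))
  expect_lt(abs(fit$log_hr - closed), 3 * fit$se)
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se)
  expect_equal(fit$hr, exp(fit$log_hr))
  expect_equal(fit$ci_low, exp(fit$log_hr - 1.96 * fit$se))
})

test_that("null exposure effects are estimated near zero", {
  set.seed(81)
  cfg <- generator_config(n_patients = 800, seed = 23, log_hr = 0,
                          contamination_rate = 0)
  coh <- generate_cohort(cfg)
  res <- run_pathway(coh$therapy, default_primary_pathway(),
                     coh$plausibility, coh$followup)
  rows <- split_person_time(res$episodes, coh$followup)
  fit <- fit_exposure_model(rows)
  expect_true(fit$estimable)
  expect_lt(abs(fit$log_hr), 3 * fit$se)
})

test_that("degenerate inputs are reported as non-estimable, not errors", {
  # everyone unexposed
  rows <- data.table(patient_id = 1:10, start = 0L, stop = 100L,
                     state = "unexposed",
                     event = c(1L, rep(0L, 9)))
  expect_false(fit_exposure_model(rows)$estimable)
  # no events at all
  rows2 <- copy(rows)[, event := 0L]
  rows2[1:5, state := "drug"]
  expect_false(fit_exposure_model(rows2)$estimable)
  # all events in one arm with no person-time contrast left
  expect_false(fit_exposure_model(rows2[state == "drug"])$estimable)
})

test_that("result summaries flag outliers and count failures", {
  res <- data.table(
    pathway = sprintf("pw%d", 1:6),
    hr = c(1.7, 1.7, 1.8, 1.75, 5.0, NA),
    se = c(0.1, 0.11, 0.12, 0.1, 0.9, NA),
    estimable = c(rep(TRUE, 5), FALSE))
  s <- summarize_results(res)
  expect_equal(s$n, 6L)
  expect_equal(s$n_nonestimable, 1L)
  expect_equal(s$median_hr, 1.75)
  expect_true("pw5" %in% s$outliers$pathway)
  expect_false("pw3" %in% s$outliers$pathway)
  # single estimable result: median is that value, no outliers
  one <- summarize_results(res[1])
  expect_equal(one$median_hr, 1.7)
  expect_equal(nrow(one$outliers), 0L)
  expect_error(summarize_results(res[6]), "no estimable")
  # absolute threshold flagging
  s2 <- summarize_results(res, hr_high = 1.78)
  expect_true(all(c("pw3", "pw5") %in% s2$outliers$pathway))
})

test_that("the two-stage experiment has the documented shape on a small cohort", {
  cfg <- generator_config(n_patients = 150, seed = 29)
  coh <- generate_cohort(cfg)
  res <- sensitivity_experiment(coh$therapy, default_registry(),
                                default_primary_pathway(), k_random = 4,
                                seed = 31, plausibility = coh$plausibility,
                                followup = coh$followup)
  expect_equal(nrow(res), 4L + 1L + 44L)
  expect_equal(sum(res$stage == "random"), 4L)
  expect_equal(sum(res$stage == "primary"), 1L)
  expect_equal(sum(res$stage == "variant"), 44L)
  expect_true(all(!is.na(res[stage == "variant", varied_node])))
  expect_true(all(res[estimable == TRUE, hr] ==
                    exp(res[estimable == TRUE, log_hr])))
})
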