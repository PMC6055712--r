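pl <- plaus_row()

test_that("node 1 options resolve implausible quantities", {
  rx <- rx_rows(1, start_date = c(0, 30), qty = c(5000, 28), ndd = 1)
  # 1b: set missing
  out <- clean_quantity(rx, "1b", "2a", pl)
  expect_true(is.na(out$qty[1]))
  expect_equal(out$qty[2], 28)
  # 1e: cap at the nearest bound
  out <- clean_quantity(rx, "1e", "2a", pl)
  expect_equal(out$qty, c(500, 28))
  low <- rx_rows(1, start_date = 0, qty = 0.2, ndd = 1)
  expect_equal(clean_quantity(low, "1e", "2a", pl)$qty, 1)
  # 1a: identity
  out <- clean_quantity(rx, "1a", "2a", pl)
  expect_equal(out$qty, rx$qty)
  # 1c: population mean of plausible values for the product
  rx3 <- rx_rows(1:3, start_date = 0, qty = c(5000, 20, 40), ndd = 1)
  expect_equal(clean_quantity(rx3, "1c", "2a", pl)$qty, c(30, 20, 40))
  # 1d: the patient's own plausible mean, falling back to the default
  rx4 <- rx_rows(c(1, 1, 2), start_date = c(0, 10, 0),
                 qty = c(5000, 30, 5000), ndd = 1)
  out <- clean_quantity(rx4, "1d", "2a", pl)
  expect_equal(out$qty, c(30, 30, 56))  # patient 2 has no donors -> default
})

test_that("node 2 options impute missing quantities", {
  # 2c: patient mean of plausible values (example: {28, 56} -> 42)
  rx <- rx_rows(1, start_date = c(0, 30, 60), qty = c(28, 56, NA), ndd = 1)
  expect_equal(clean_quantity(rx, "1a", "2c", pl)$qty[3], 42)
  # 2a leaves missing
  expect_true(is.na(clean_quantity(rx, "1a", "2a", pl)$qty[3]))
  # 2b population mean across patients, per product
  rx2 <- rx_rows(1:3, start_date = 0, qty = c(10, 30, NA), ndd = 1)
  expect_equal(clean_quantity(rx2, "1a", "2b", pl)$qty[3], 20)
  # 2d carries the previous plausible value forward, in start-date order
  rx3 <- rx_rows(1, start_date = c(0, 10, 20), qty = c(12, NA, NA), ndd = 1)
  expect_equal(clean_quantity(rx3, "1a", "2d", pl)$qty, c(12, 12, 12))
  # 2d with no prior prescription leaves missing
  rx4 <- rx_rows(1, start_date = c(0, 10), qty = c(NA, 12), ndd = 1)
  out <- clean_quantity(rx4, "1a", "2d", pl)
  expect_true(is.na(out$qty[1]))
  # 2e product default
  expect_equal(clean_quantity(rx4, "1a", "2e", pl)$qty[1], 56)
})

test_that("implausible values set missing at node 1 flow into node 2", {
  rx <- rx_rows(1, start_date = c(0, 10), qty = c(5000, 20), ndd = 1)
  out <- clean_quantity(rx, "1b", "2b", pl)
  expect_equal(out$qty, c(20, 20))  # population mean excludes the 5000
})

test_that("node 3/4 mirror the quantity logic for ndd", {
  rx <- rx_rows(1, start_date = c(0, 30, 60), qty = 28,
                ndd = c(0, 2, NA))
  # 3b: below ndd_min -> missing
  out <- clean_daily_dose(rx, "3b", "4a", pl)
  expect_true(is.na(out$ndd[1]))
  expect_true(is.na(out$ndd[3]))
  # 4c: population mean for the product {1, 2, 3} -> 2
  rx2 <- rx_rows(1:4, start_date = 0, qty = 28, ndd = c(1, 2, 3, NA))
  expect_equal(clean_daily_dose(rx2, "3a", "4c", pl)$ndd[4], 2)
  # 4b: patient mean
  rx3 <- rx_rows(1, start_date = c(0, 10, 20), qty = 28, ndd = c(1, 2, NA))
  expect_equal(clean_daily_dose(rx3, "3a", "4b", pl)$ndd[3], 1.5)
  # snapshot semantics: implausible donors are excluded from the mean
  rx4 <- rx_rows(1, start_date = c(0, 10, 20), qty = 28, ndd = c(1, 0, NA))
  expect_equal(clean_daily_dose(rx4, "3b", "4b", pl)$ndd[3], 1)
})

test_that("node 5 cleans both duration fields independently", {
  rx <- rx_rows(1, start_date = c(0, 30), qty = 28, ndd = 1,
                numdays = c(999, 28), dose_duration = c(999, NA))
  # 5c: cap at dur_max
  out <- clean_duration_fields(rx, "5c", pl)
  expect_equal(out$numdays, c(186, 28))
  expect_equal(out$dose_duration[1], 186)
  # 5b: set missing; in-bounds values untouched
  out <- clean_duration_fields(rx, "5b", pl)
  expect_true(is.na(out$numdays[1]))
  expect_equal(out$numdays[2], 28)
  # 5d: population mean of plausible durations, rounded half-up
  rx2 <- rx_rows(1:3, start_date = 0, qty = 28, ndd = 1,
                 numdays = c(999, 28, 29))
  expect_equal(clean_duration_fields(rx2, "5d", pl)$numdays[1],
               round_half_up(mean(c(28, 29))))
})

test_that("Step A is idempotent, conserves records, and leave-options are identities", {
  set.seed(42)
  n <- 120
  rx <- rx_rows(sample(1:10, n, TRUE),
                product_code = sample(c("P1", "P2"), n, TRUE),
                start_date = sample(0:300, n, TRUE),
                qty = sample(c(NA, 1, 28, 56, 5000), n, TRUE),
                ndd = sample(c(NA, 0, 1, 2), n, TRUE),
                numdays = sample(c(NA, 28, 999), n, TRUE),
                dose_duration = sample(c(NA, 28, 999), n, TRUE))
  pl2 <- rbind(plaus_row("P1"), plaus_row("P2"))
  for (opts in list(c("1b", "2b"), c("1c", "2c"), c("1d", "2d"),
                    c("1e", "2e"))) {
    once <- clean_quantity(rx, opts[1], opts[2], pl2)
    twice <- clean_quantity(once, opts[1], opts[2], pl2)
    expect_equal(twice, once)
    expect_equal(nrow(once), n)
  }
  for (opt5 in c("5b", "5c", "5d", "5e")) {
    once <- clean_duration_fields(rx, opt5, pl2)
    expect_equal(clean_duration_fields(once, opt5, pl2), once)
    expect_equal(nrow(once), n)
  }
  # all-leave options are the identity
  expect_equal(clean_quantity(rx, "1a", "2a", pl2), rx)
  expect_equal(clean_daily_dose(rx, "3a", "4a", pl2), rx)
  expect_equal(clean_duration_fields(rx, "5a", pl2), rx)
})

test_that("unknown product codes are treated as fully plausible with a warning", {
  rx <- rx_rows(1, product_code = "MYSTERY", start_date = 0, qty = 99999,
                ndd = 1)
  expect_warning(out <- clean_quantity(rx, "1b", "2a", pl),
                 "no plausibility entry")
  expect_equal(out$qty, 99999)
})

test_that("cleaning updates the ledger with modification counts", {
  led <- new_ledger()
  rx <- rx_rows(1, start_date = c(0, 10, 20), qty = c(5000, NA, 28), ndd = 1)
  clean_quantity(rx, "1b", "2e", pl, ledger = led)
  tab <- ledger_table(led)
  expect_equal(tab$node, c("1", "2"))
  expect_equal(tab$records_set_missing[1], 1L)
  expect_equal(tab$records_modified[2], 2L)  # the NA and the 1b-casualty
  expect_equal(tab$records_dropped, c(0L, 0L))
})
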