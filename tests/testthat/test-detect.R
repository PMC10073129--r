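test_that("open-pore current estimation finds the baseline population", {
  # constant trace
  tr <- IonTrace(rep(500, 5000), 10000, 100)
  expect_equal(estimateOpenCurrent(tr), 500)
  # baseline + events
  set.seed(31)
  tr <- IonTrace(c(rnorm(6000, 500, 5), rnorm(4000, 174, 5)), 10000, 100)
  expect_equal(estimateOpenCurrent(tr), 500, tolerance = 1e-3)
  # synthetic generator trace
  co <- makeCohort("free", n_events = 20, seed = 51)
  expect_equal(co$io, 500, tolerance = 2e-3)
  # (nearly) all-blocked trace: baseline population below 10% is an error
  set.seed(32)
  bad <- IonTrace(c(rnorm(9700, 174, 5), rnorm(300, 500, 5)), 10000, 100)
  expect_error(estimateOpenCurrent(bad), "baseline")
})

test_that("detection on noiseless rectangular trains is sample-exact", {
  sim <- generateEventTrain(freeProteinProfile(), NoiseModel(0), Io = 500,
                            sampling_rate = 25000, duration = 5, seed = 41,
                            min_event_s = 0.02)
  ev <- detectEvents(sim$trace, 500)
  tru <- sim$annotation$events
  expect_equal(nrow(ev), nrow(tru))
  expect_identical(ev$start, tru$start)
  expect_identical(ev$end, tru$end)
  # detection is idempotent
  ev2 <- detectEvents(sim$trace, 500)
  expect_identical(ev, ev2)
  # events are ordered and non-overlapping
  expect_true(all(ev$start[-1] >= ev$end[-nrow(ev)]))
})

test_that("detection on noisy filtered traces recovers nearly all events", {
  co <- makeCohort("free", n_events = 50, seed = 61, segment = FALSE)
  tru <- co$sim$annotation$events
  ev <- co$events
  # >= 99% recovery: every true event matched by one detected event
  matched <- vapply(seq_len(nrow(tru)), function(i) {
    any(ev$start < tru$end[i] & ev$end > tru$start[i])
  }, TRUE)
  expect_gte(mean(matched), 0.99)
  # median boundary error within half a filter rise time budget:
  # 1/(2 * cutoff) seconds at the 10 kHz hardware filter
  ds <- vapply(seq_len(nrow(tru)), function(i) {
    j <- which(ev$start < tru$end[i] & ev$end > tru$start[i])[1]
    if (is.na(j)) return(NA_real_)
    abs(ev$start[j] - tru$start[i]) / co$fs
  }, 0)
  expect_lte(median(ds, na.rm = TRUE), 1 / (2 * co$hw))
})

test_that("flat traces yield no events and bad thresholds error", {
  tr <- IonTrace(rnorm(5000, 500, 5), 10000, 100)
  expect_equal(nrow(detectEvents(tr, 500)), 0)
  expect_error(detectEvents(tr, -5), "Io")
  expect_error(detectEvents(tr, 500, entry_threshold = 0.97), "entry")
})

test_that("blockade statistics: arithmetic, fit and bimodality guard", {
  # all events at 174 pA residual of Io = 500 -> blockade 65.2%
  ev <- data.frame(blockade_pct = rep(100 * (500 - 174) / 500, 30))
  bs <- blockadeStatistics(ev)
  expect_equal(bs$blockade_pct, 65.2, tolerance = 1e-6)
  expect_false(bs$multimodal)
  # two well-separated subpopulations raise the flag
  set.seed(71)
  ev2 <- data.frame(blockade_pct = c(rnorm(60, 51, 0.5), rnorm(60, 65, 0.5)))
  expect_true(blockadeStatistics(ev2)$multimodal)
  expect_error(blockadeStatistics(ev[1:5, , drop = FALSE]), "at least")
})

test_that("dwell kinetics recover exponential time constants", {
  set.seed(81)
  n <- 500
  ev <- data.frame(dwell_s = rexp(n, 1 / 0.010))
  gaps <- rexp(n, 1 / 0.050)
  k <- dwellKinetics(ev, inter_event_s = gaps)
  expect_lt(abs(k$tau_off_s - 0.010), 2 * 0.010 / sqrt(n) + 2 * k$tau_off_se)
  expect_lt(abs(k$tau_on_s - 0.050), 2 * 0.050 / sqrt(n) + 2 * k$tau_on_se)
  expect_equal(k$capture_rate_hz, 1 / k$tau_on_s)
  # doubling the capture rate doubles 1/tau_on within error
  gaps2 <- rexp(n, 2 / 0.050)
  k2 <- dwellKinetics(ev, inter_event_s = gaps2)
  expect_equal(k2$capture_rate_hz / k$capture_rate_hz, 2, tolerance = 0.15)
  expect_error(dwellKinetics(ev[1, , drop = FALSE], gaps), "at least")
})
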