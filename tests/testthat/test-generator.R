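test_that("position-to-current map hits the residence-site anchors", {
  map <- defaultCurrentMap(500)
  expect_equal(positionToCurrent(4, map), 0.348 * 500)   # deep site, ~35%
  expect_equal(positionToCurrent(10, map), 0.728 * 500)  # shallow site
  # post-escape samples emit the open-pore current
  expect_equal(positionToCurrent(NA, map), 500)
  # clamped extrapolation and monotonicity
  expect_equal(positionToCurrent(1, map), positionToCurrent(2.5, map))
  zs <- seq(2, 13, 0.25)
  expect_true(all(diff(positionToCurrent(zs, map)) >= 0))
})

test_that("switching-rate calibration matches the analytic band variance", {
  prof <- bakBH3ComplexProfile()
  lev <- levelResiduals(prof) / 100 * 500
  occ <- levelOccupancies(prof)
  v <- sum(occ * lev^2) - sum(occ * lev)^2
  lam <- prof@switchRate
  # Lorentzian band variance through the analysis Bessel equals target^2
  f <- seq(0, 5000, 0.25)
  w <- nanofp:::.besselMag2(f, 100)
  got <- sum(4 * v * lam / (lam^2 + (2 * pi * f)^2) * w) * 0.25
  expect_equal(sqrt(got), 78.9, tolerance = 0.01)
  # unreachable targets (above the total switching RMS) are refused
  expect_error(calibrateSwitchingRate(prof, sqrt(v) * 1.01), "unreachable")
})

test_that("event train: durations, occupancies and annotations agree", {
  prof <- freeProteinProfile()
  sim <- generateEventTrain(prof, NoiseModel(0), Io = 500,
                            sampling_rate = 25000, duration = 2, seed = 21,
                            n_events = 150)
  ev <- sim$annotation$events
  seg <- sim$annotation$segments
  expect_gte(nrow(ev), 150)
  # durations: exponential with mean tau_off (SE = tau/sqrt(n))
  dw <- (ev$end - ev$start) / 25000
  expect_lt(abs(mean(dw) - prof@tauOff),
            3 * prof@tauOff / sqrt(nrow(ev)))
  # segments tile each event without overlap
  for (e in ev$event_id[1:10]) {
    s <- seg[seg$event_id == e, ]
    expect_equal(s$start[1], ev$start[ev$event_id == e])
    expect_equal(s$end[nrow(s)], ev$end[ev$event_id == e])
    if (nrow(s) > 1) expect_true(all(s$start[-1] == s$end[-nrow(s)]))
  }
  # CTMC long-run occupancies equal the configured stationary distribution
  tt <- tapply(seg$end - seg$start, seg$level, sum)
  occ_hat <- as.numeric(tt[paste0("L", 1:3)]) / sum(tt)
  # effective number of independent visits per level ~ number of segments
  nseg <- as.numeric(table(seg$level)[paste0("L", 1:3)])
  tol <- 3 * sqrt(prof@occupancies * (1 - prof@occupancies)) /
    sqrt(pmax(nseg, 1))
  expect_true(all(abs(occ_hat - prof@occupancies) < tol + 0.01))
  # noiseless trace: level means over annotated segments are exact
  x <- traceCurrent(sim$trace)
  for (i in sample(nrow(seg), 25)) {
    mu <- mean(x[(seg$start[i] + 1):seg$end[i]])
    expect_equal(mu, 500 * seg$ires_pct[i] / 100, tolerance = 1e-12)
  }
})

test_that("zero switching with one level gives rectangular pulses", {
  prof <- AnalyteProfile("rect", 40, 1, switch_rate = 0, tau_off = 0.05,
                         capture_rate = 20)
  sim <- generateEventTrain(prof, NoiseModel(0), Io = 500,
                            sampling_rate = 10000, duration = 2, seed = 3)
  x <- traceCurrent(sim$trace)
  expect_setequal(unique(x), c(500, 200))
  ev <- sim$annotation$events
  for (e in seq_len(nrow(ev)))
    expect_true(all(x[(ev$start[e] + 1):ev$end[e]] == 200))
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- generateEventTrain(freeProteinProfile(), NoiseModel(10), Io = 500,
                          sampling_rate = 25000, duration = 1, seed = 77,
                          hardware_cutoff = 5000)
  b <- generateEventTrain(freeProteinProfile(), NoiseModel(10), Io = 500,
                          sampling_rate = 25000, duration = 1, seed = 77,
                          hardware_cutoff = 5000)
  expect_identical(traceCurrent(a$trace), traceCurrent(b$trace))
  expect_identical(a$annotation, b$annotation)
})

test_that("flicker noise has the configured 1/f spectral shape", {
  set.seed(8)
  x <- nanofp:::.flickerNoise(2^16, 1000, amp = 100, alpha = 1)
  sp <- eventPeriodogram(x, 1000)
  f <- psdFrequencies(sp); p <- psdValues(sp)
  sel <- f > 0.5 & f < 100
  fit <- stats::lm(log(p[sel]) ~ log(f[sel]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.15)
})

test_that("rate-matrix consistency checking works", {
  occ <- c(0.2, 0.8)
  Q <- 100 * (matrix(occ, 2, 2, byrow = TRUE) - diag(2))
  expect_silent(checkStationary(Q, occ))
  expect_error(checkStationary(Q, c(0.5, 0.5)), "does not match")
  expect_error(checkStationary(matrix(1, 2, 2), occ), "sum to 0")
})

test_that("titration counts follow the one-site curve", {
  concs <- c(1, 2, 5, 10, 20, 50, 100, 200, 500)
  # X = KD -> expected F_c = Bmax/2; saturation -> ~Bmax
  ts <- generateTitration(KD = 20, Bmax = 0.9, concentrations = c(20, 1e5),
                          events_per_point = 4000, seed = 1)
  tb <- titrationTable(ts)
  expect_lt(abs(tb$fc_pct[1] - 45), 3 * 100 * sqrt(0.45 * 0.55 / 4000))
  expect_lt(abs(tb$fc_pct[2] - 90), 3 * 100 * sqrt(0.9 * 0.1 / 4000))
  # empirical F_c converges on the curve as events_per_point grows
  for (n in c(50, 500, 5000)) {
    tb <- titrationTable(
      suppressWarnings(generateTitration(19, 1.11, concs, n, seed = 2)))
    p <- pmin(1, 1.11 * concs / (19 + concs))
    expect_true(all(abs(tb$fc_pct / 100 - p) <
                      4 * sqrt(pmax(p * (1 - p), 1e-4) / n)))
  }
  expect_warning(generateTitration(19, 1.11, c(10, 500), 100, seed = 1),
                 "capped")
})

test_that("competition time-course follows first-order displacement", {
  # k = 0: initial population stays at 100%
  cc <- generateCompetitionTimecourse("a", "b", 0, c(0, 100, 1000), 500,
                                      seed = 4)
  expect_true(all(cc$frac_new_pct == 0))
  # displaced fraction at the half-life is ~50%
  k <- 0.002
  cc <- generateCompetitionTimecourse("a", "b", k, log(2) / k, 2000,
                                      seed = 5)
  expect_lt(abs(cc$frac_new_pct - 50), 3 * 100 * sqrt(0.25 / 2000))
  # an exponential fit to generated fractions recovers k
  tt <- c(60, 240, 600, 1200, 2400, 4800)
  cc <- generateCompetitionTimecourse("a", "b", 0.0008, tt, 1500, seed = 6)
  fit <- minpack.lm::nlsLM(frac_new_pct / 100 ~ 1 - exp(-k * time_s),
                           data = cc, start = list(k = 0.001))
  expect_equal(coef(fit)[["k"]], 0.0008, tolerance = 0.1)
})
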