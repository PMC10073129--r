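test_that("fingerprints of identical noise-free events coincide", {
  prof <- AnalyteProfile("flat", 34.8, 1, switch_rate = 0, tau_off = 0.5,
                         capture_rate = 4)
  sim <- generateEventTrain(prof, NoiseModel(0), Io = 500,
                            sampling_rate = 10000, duration = 4, seed = 16,
                            min_event_s = 0.3)
  ev <- detectEvents(sim$trace, 500)
  fp <- fingerprintEvents(ev, sim$trace)
  expect_true(all(abs(fp$dio_pct - 65.2) < 1e-9))
  expect_true(all(fp$in_pA < 1e-9))
})

test_that("reference normalization centres the free cohort at (1, 1)", {
  co <- makeCohort("free", n_events = 25, seed = 120, segment = FALSE)
  fp <- fingerprintEvents(co$events, co$sim$trace)
  fpn <- fingerprintEvents(co$events, co$sim$trace, reference = fp)
  expect_equal(mean(fpn$dio_norm), 1, tolerance = 0.02)
  expect_equal(mean(fpn$in_norm), 1, tolerance = 0.02)
})

test_that("mixture model separates two configured populations", {
  cof <- makeCohort("free", n_events = 25, seed = 120, segment = FALSE)
  cob <- makeCohort("bak", n_events = 25, seed = 121, segment = FALSE)
  fp <- rbind(
    fingerprintEvents(cof$events, cof$sim$trace, label = "free"),
    fingerprintEvents(cob$events, cob$sim$trace, label = "bak"))
  model <- fitPopulations(fp, K = 2, seed = 1)
  cls <- classifyEvents(fp, model)
  tab <- table(cls$label, cls$population)
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.99)
  # K = 1: everything is one population
  m1 <- fitPopulations(fp, K = 1, seed = 1)
  expect_equal(unique(classifyEvents(fp, m1)$population), 1)
  # classification is deterministic given the model
  expect_identical(classifyEvents(fp, model), cls)
  expect_error(fitPopulations(fp[1:5, ], K = 2), "at least")
})

test_that("classification accuracy grows with cluster separation", {
  set.seed(17)
  acc <- vapply(c(1, 3, 6), function(d) {
    pts <- data.frame(
      dio_pct = c(rnorm(150, 60), rnorm(150, 60 + d)),
      in_pA = c(rnorm(150, 20), rnorm(150, 20 + d)),
      label = rep(c("a", "b"), each = 150))
    m <- fitPopulations(pts, K = 2, seed = 2)
    cl <- classifyEvents(pts, m)
    tab <- table(cl$label, cl$population)
    sum(apply(tab, 2, max)) / sum(tab)
  }, 0)
  expect_true(all(diff(acc) >= -0.01))
  expect_gt(acc[3], 0.99)
})

test_that("population time-courses follow the displacement kinetics", {
  # fractions sum to 100 per window; k = 0 stays constant
  set.seed(18)
  pts <- data.frame(wall_time_s = runif(600, 0, 300),
                    population = sample(1:2, 600, TRUE, prob = c(0.7, 0.3)))
  tc <- populationTimecourse(pts, window = 60)
  sums <- rowSums(tc[, grep("^frac_", names(tc))])
  expect_true(all(abs(sums[tc$n > 0] - 100) < 1e-9))
  # first-order displacement recovered from windowed fractions
  k <- 0.003
  tt <- seq(30, 1800, by = 60)
  cc <- generateCompetitionTimecourse("initial", "new", k, tt, 400,
                                      seed = 19)
  fit <- minpack.lm::nlsLM(frac_new_pct / 100 ~ 1 - exp(-kk * time_s),
                           data = cc, start = list(kk = 0.001))
  expect_equal(coef(fit)[["kk"]], k, tolerance = 0.08)
})

test_that("bound fractions are exact ratios with guarded domains", {
  expect_equal(boundFraction(50, 100), 50)
  expect_equal(boundFraction(0, 33), 0)
  expect_equal(boundFraction(466, 466), 100)
  expect_error(boundFraction(5, 0), "n_total")
  expect_error(boundFraction(7, 5), "n_comp")
})

test_that("one-site fit inverts noise-free binding data to 6 digits", {
  X <- c(2, 5, 10, 20, 50, 100, 200, 300)
  Y <- 1.10 * X / (38 + X)
  fit <- fitBinding(data.frame(conc_nM = X, fc_pct = 100 * Y))
  expect_equal(fit$KD_nM, 38, tolerance = 1e-7)
  expect_equal(fit$Bmax, 1.10, tolerance = 1e-7)
  expect_true(fit$KD_ci[1] <= fit$KD_nM && fit$KD_nM <= fit$KD_ci[2])
  # degenerate designs are refused
  expect_error(fitBinding(data.frame(conc_nM = c(500, 600, 700, 800),
                                     fc_pct = c(99, 99.2, 99.4, 99.5))),
               "curvature")
  expect_error(fitBinding(data.frame(conc_nM = c(1, 2), fc_pct = c(5, 9))),
               "concentrations")
})

test_that("halving the event count per point widens the K_D interval", {
  concs <- c(1, 2, 5, 10, 20, 50, 100, 200, 500)
  widths <- vapply(1:6, function(s) {
    big <- suppressWarnings(generateTitration(19, 1.11, concs, 600,
                                              seed = s))
    small <- suppressWarnings(generateTitration(19, 1.11, concs, 150,
                                                seed = s + 100))
    diff(fitBinding(small)$KD_ci) / diff(fitBinding(big)$KD_ci)
  }, 0)
  expect_gt(median(widths), 1)
})
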