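# Shared synthetic cohorts, generated once per test run and memoized.
# Acquisition choices per cohort follow the switching speed of the
# analyte: the free protein (lambda ~ 2.8e3 /s) needs 10 kHz bandwidth
# at 50 kHz sampling; the slow-switching Bak-BH3 complex is resolved at
# 5 kHz bandwidth / 25 kHz sampling.

.cohort_cache <- new.env(parent = emptyenv())

makeCohort <- function(which = c("free", "bak"), n_events = 60, seed = 11,
                       segment = TRUE) {
  which <- match.arg(which)
  key <- paste(which, n_events, seed, segment, sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  if (which == "free") {
    prof <- freeProteinProfile(); fs <- 50000; hw <- 10000; minev <- 0.05
  } else {
    prof <- bakBH3ComplexProfile(); fs <- 25000; hw <- 5000; minev <- 0.25
  }
  sim <- generateEventTrain(prof, NoiseModel(10), Io = 500,
                            sampling_rate = fs, duration = 1, seed = seed,
                            min_event_s = minev, hardware_cutoff = hw,
                            n_events = n_events)
  io <- estimateOpenCurrent(sim$trace)
  ev <- detectEvents(sim$trace, io, min_duration = 0.02)
  segs <- NULL
  if (segment)
    segs <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
      segmentLevels(ev[i, ], sim$trace)))
  out <- list(profile = prof, sim = sim, io = io, events = ev,
              segments = segs, fs = fs, hw = hw)
  .cohort_cache[[key]] <- out
  out
}

# time-in-level occupancy per event (ranked levels), for SE estimates
eventOccupancies <- function(segments, levels = c("L1", "L2", "L3")) {
  ids <- unique(segments$event_id)
  t(vapply(ids, function(e) {
    s <- segments[segments$event_id == e, ]
    tt <- vapply(levels, function(L)
      sum(s$duration_s[s$level == L]), 0)
    tt / sum(tt)
  }, numeric(length(levels))))
}

# bootstrap SE of the cohort (time-weighted) occupancy of one level
cohortOccSE <- function(segments, level, B = 300, seed = 1) {
  set.seed(seed)
  ids <- unique(segments$event_id)
  tot <- vapply(ids, function(e)
    sum(segments$duration_s[segments$event_id == e]), 0)
  lv <- vapply(ids, function(e) {
    s <- segments[segments$event_id == e, ]
    sum(s$duration_s[s$level == level])
  }, 0)
  stats::sd(replicate(B, {
    i <- sample(length(ids), replace = TRUE)
    100 * sum(lv[i]) / sum(tot[i])
  }))
}
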