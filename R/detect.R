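## Event detection: open-pore current estimation, hysteresis thresholding,
## blockade and dwell statistics.

# kernel-density peak finder shared by the baseline estimator and the
# level segmentation: local maxima above min_frac of the tallest peak,
# with shallow-valley (prominence) merging
.densityPeaks <- function(x, min_frac = 0.02, valley_ratio = 0.5,
                          n_grid = 512) {
  if (stats::sd(x) == 0)
    return(list(grid = x[1], dens = 1, peaks = 1L))
  # bandwidth: the default rule collapses discrete (noise-free) levels into
  # one broad kernel; bound it by the within-level noise scale estimated
  # from first differences, with a floor of 1/256 of the amplitude range
  bw0 <- stats::bw.nrd0(x)
  bw1 <- max(stats::mad(diff(x)) / sqrt(2), diff(range(x)) / 256)
  d <- stats::density(x, bw = min(bw0, bw1), n = n_grid)
  y <- d$y; g <- d$x
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] >= min_frac * max(y)]
  if (length(pk) == 0) pk <- which.max(y)
  repeat {
    if (length(pk) <= 1) break
    hts <- y[pk]
    valleys <- vapply(seq_len(length(pk) - 1),
                      function(i) min(y[pk[i]:pk[i + 1]]), 0)
    shallow <- which(valleys > valley_ratio *
                       pmin(hts[-length(hts)], hts[-1]))
    if (length(shallow) == 0) break
    i <- shallow[1]
    pk <- pk[-(if (hts[i] < hts[i + 1]) i else i + 1)]
  }
  list(grid = g, dens = y, peaks = pk)
}

#' Estimate the open-pore current from a trace
#'
#' Locates the baseline (open-pore) amplitude population as the
#' highest-current peak of the sample amplitude density, requires it to
#' carry at least `min_baseline_frac` of the samples, and refines the
#' peak location by the mean of the samples in a window of +/- 3 robust
#' SDs around it (equivalent to the centre of a Gaussian fit to the
#' baseline histogram peak).
#'
#' @param trace an [IonTrace-class].
#' @param min_baseline_frac minimum fraction of samples that must belong
#'   to the baseline population (default 0.1).
#' @param max_samples subsample cap for the density estimate.
#' @return Open-pore current Io, pA.
#' @examples
#' tr <- IonTrace(c(rnorm(900, 500, 5), rnorm(100, 170, 5)), 1e4, 100)
#' estimateOpenCurrent(tr)
#' @export
estimateOpenCurrent <- function(trace, min_baseline_frac = 0.1,
                                max_samples = 2e5) {
  stopifnot(is(trace, "IonTrace"))
  x <- traceCurrent(trace)
  xs <- if (length(x) > max_samples)
    x[seq(1L, length(x), length.out = max_samples)] else x
  dp <- .densityPeaks(xs)
  top <- dp$peaks[length(dp$peaks)]           # highest-current peak
  mu0 <- dp$grid[top]
  # population boundary: valley below the top peak (or -Inf if single)
  lo <- if (length(dp$peaks) > 1) {
    prev <- dp$peaks[length(dp$peaks) - 1]
    vi <- prev:top
    dp$grid[vi[which.min(dp$dens[vi])]]
  } else -Inf
  base <- xs[xs > lo]
  if (length(base) / length(xs) < min_baseline_frac)
    stop("no resolvable open-pore baseline population ",
         sprintf("(top amplitude peak holds %.1f%% of samples)",
                 100 * length(base) / length(xs)))
  s <- stats::mad(base)
  if (s == 0) return(mu0)
  mu <- mu0
  for (i in 1:3) {                 # re-centred trimmed mean of the peak
    core <- base[abs(base - mu) < 3 * s]
    if (length(core) < 10) core <- base
    mu <- mean(core)
  }
  mu
}

#' Detect capture-trap-escape events by hysteresis thresholding
#'
#' Events are maximal intervals during which the current stays below
#' `exit_threshold * Io` and that dip below `entry_threshold * Io` at
#' least once (hysteresis: the entry threshold triggers, the exit
#' threshold delimits). Intervals shorter than `min_duration` are
#' discarded. Boundaries are 0-based, half-open sample indices.
#'
#' @param trace an [IonTrace-class].
#' @param Io open-pore current, pA (e.g. from [estimateOpenCurrent()]).
#' @param entry_threshold trigger threshold, fraction of Io (default
#'   0.85).
#' @param exit_threshold delimiting threshold, fraction of Io (default
#'   0.95); must exceed `entry_threshold`.
#' @param min_duration minimum event duration, s.
#' @return data.frame with one row per event: `event_id`, `start`, `end`
#'   (0-based half-open), `io_local`, `dwell_s`, `blockade_pct`
#'   (median-current blockade, percent), `ires_pct` (= 100 -
#'   blockade_pct).
#' @export
detectEvents <- function(trace, Io, entry_threshold = 0.85,
                         exit_threshold = 0.95, min_duration = 0) {
  stopifnot(is(trace, "IonTrace"))
  if (Io <= 0) stop("Io must be > 0")
  if (!(entry_threshold > 0 && entry_threshold < exit_threshold &&
        exit_threshold < 1))
    stop("need 0 < entry_threshold < exit_threshold < 1")
  x <- traceCurrent(trace)
  fs <- samplingRate(trace)
  below_exit <- x < exit_threshold * Io
  r <- rle(below_exit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- list()
  for (i in keep) {
    a <- starts[i]; b <- ends[i]
    if ((b - a + 1L) / fs < min_duration) next
    seg <- x[a:b]
    if (!any(seg < entry_threshold * Io)) next
    med <- stats::median(seg)
    rows[[length(rows) + 1L]] <- data.frame(
      start = a - 1L, end = b,                 # 0-based half-open
      io_local = Io,
      dwell_s = (b - a + 1L) / fs,
      blockade_pct = 100 * (Io - med) / Io,
      ires_pct = 100 * med / Io)
  }
  if (!length(rows))
    return(data.frame(event_id = integer(), start = integer(),
                      end = integer(), io_local = numeric(),
                      dwell_s = numeric(), blockade_pct = numeric(),
                      ires_pct = numeric()))
  out <- do.call(rbind, rows)
  out <- cbind(event_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Gaussian fit to a histogram peak; returns mean, sd, ok flag
.gaussHistFit <- function(v, bins = 40) {
  h <- graphics::hist(v, breaks = bins, plot = FALSE)
  xm <- h$mids; yc <- h$counts
  st <- list(A = max(yc), mu = xm[which.max(yc)],
             s = max(stats::sd(v), diff(xm[1:2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(yc ~ A * exp(-(xm - mu)^2 / (2 * s^2)), start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  # bimodality guard: two peaks above half the main one with a deep
  # valley between them
  pk <- which(diff(sign(diff(yc))) == -2) + 1
  tall <- pk[yc[pk] >= 0.5 * max(yc)]
  multimodal <- FALSE
  if (length(tall) > 1) {
    i1 <- min(tall); i2 <- max(tall)
    multimodal <- i2 - i1 >= 3 &&
      min(yc[i1:i2]) < 0.3 * min(yc[i1], yc[i2])
  }
  if (is.null(fit))
    return(list(mean = mean(v), sd = stats::sd(v), ok = FALSE,
                multimodal = multimodal))
  cf <- stats::coef(fit)
  list(mean = cf[["mu"]], sd = abs(cf[["s"]]), ok = TRUE,
       multimodal = multimodal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort blockade statistics
#'
#' Gaussian fit to the histogram of per-event blockades (the peak value
#' is the cohort blockade, the fitted sigma its width). Falls back to
#' the sample mean, with `fit_ok = FALSE`, when the histogram is
#' degenerate; a `multimodal` flag is raised when a second comparable
#' peak is present.
#'
#' @param events event table from [detectEvents()] (needs
#'   `blockade_pct`).
#' @param min_events minimum cohort size for a fit (default 20).
#' @return list with `blockade_pct`, `sigma_pct`, `fit_ok`,
#'   `multimodal`, `n`.
#' @export
blockadeStatistics <- function(events, min_events = 20) {
  v <- events$blockade_pct
  if (length(v) < min_events)
    stop("need at least ", min_events, " events for a blockade fit")
  f <- .gaussHistFit(v)
  list(blockade_pct = unname(f$mean), sigma_pct = unname(f$sd),
       fit_ok = f$ok, multimodal = f$multimodal, n = length(v))
}

# exponential decay fit to a histogram of waiting times; falls back to the
# ML mean. Returns tau and its standard error.
.expFit <- function(t) {
  n <- length(t)
  tau_ml <- mean(t)
  h <- graphics::hist(t, breaks = 30, plot = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(h$counts ~ A * exp(-h$mids / tau),
                      start = list(A = max(h$counts), tau = tau_ml)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(tau = tau_ml, se = tau_ml / sqrt(n)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) tau_ml / sqrt(n))
  list(tau = unname(cf[["tau"]]), se = unname(se))
}

#' Dwell-time and capture kinetics
#'
#' tau_off from a single-exponential fit to the dwell-time histogram,
#' tau_on from the same fit to inter-event (open-pore) intervals, and
#' the capture rate 1/tau_on.
#'
#' @param events event table from [detectEvents()].
#' @param inter_event_s inter-event waiting times, s. If NULL they are
#'   derived from the event boundaries (gaps between consecutive events,
#'   requires `sampling_rate`).
#' @param sampling_rate Hz; needed only when deriving gaps.
#' @param min_events minimum number of events (default 20).
#' @return list with `tau_off_s`, `tau_off_se`, `tau_on_s`,
#'   `tau_on_se`, `capture_rate_hz`, `event_count`.
#' @export
dwellKinetics <- function(events, inter_event_s = NULL,
                          sampling_rate = NULL, min_events = 20) {
  if (nrow(events) < min_events)
    stop("need at least ", min_events, " events for kinetics")
  if (is.null(inter_event_s)) {
    if (is.null(sampling_rate))
      stop("sampling_rate required to derive inter-event intervals")
    gaps <- (events$start[-1] - events$end[-nrow(events)]) / sampling_rate
    inter_event_s <- gaps[gaps > 0]
  }
  off <- .expFit(events$dwell_s)
  on <- .expFit(inter_event_s)
  list(tau_off_s = off$tau, tau_off_se = off$se,
       tau_on_s = on$tau, tau_on_se = on$se,
       capture_rate_hz = 1 / on$tau, event_count = nrow(events))
}
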