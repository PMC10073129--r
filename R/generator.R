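## Synthetic-trace generation: position->current mapping, calibrated CTMC
## level-switching event trains, noise synthesis, titrations, competition
## time-courses.

#' Map a positional trajectory to an ideal current trace
#'
#' Interpolates the residual-current fraction of a [CurrentMap-class]
#' linearly (and monotonically) over z, clamping outside the anchored
#' range, and multiplies by the open-pore current. Samples after escape
#' (NA positions, or positions past the map's last anchor when
#' `escaped = TRUE` semantics are handled by the caller) emit the
#' open-pore current.
#'
#' @param z positions, nm; NA marks post-escape samples.
#' @param map a [CurrentMap-class].
#' @return Ideal (noise-free) current, pA.
#' @examples
#' positionToCurrent(c(4, 10, NA), defaultCurrentMap(500))
#' @export
positionToCurrent <- function(z, map = defaultCurrentMap()) {
  stopifnot(is(map, "CurrentMap"))
  res <- stats::approx(map@z, map@residualPct, xout = z, rule = 2)$y
  out <- res / 100 * map@openPoreCurrent
  out[is.na(z)] <- map@openPoreCurrent
  out
}

## ---------------------------------------------------------- calibration

# stationary distribution of a CTMC rate matrix (rows sum to zero)
.statDist <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- qr.solve(A, b)
  p / sum(p)
}

# total stationary variance (pA^2) of the level-switching telegraph signal
.telegraphVariance <- function(profile, Io) {
  lev <- profile@levelResidualPct / 100 * Io
  p <- profile@occupancies
  sum(p * lev^2) - sum(p * lev)^2
}

#' Calibrate the level-switching rate to a target band noise
#'
#' For the jump-to-stationary switching chain the current autocovariance
#' is a single exponential with rate lambda, so its one-sided PSD is the
#' Lorentzian \eqn{S(f) = 4 v \lambda / (\lambda^2 + (2\pi f)^2)} with v
#' the stationary variance set by the levels and occupancies. The
#' measured I_N at a cutoff is the square root of this spectrum
#' integrated through the analysis filter, so the calibration solves
#' \deqn{\int_0^\infty S(f;\lambda)\, |H_{Bessel}(f; f_c)|^2 \, df =
#'       I_N^{target\,2}}
#' for lambda, where H is the analog 8-pole Bessel response of the
#' analysis refilter. Using the filter-weighted band (rather than a
#' brickwall 0..fc integral) matches how I_N is actually measured.
#'
#' @param profile an [AnalyteProfile-class] (levels + occupancies used).
#' @param target_in target I_N at the analysis cutoff, pA.
#' @param cutoff analysis filter cutoff, Hz (default 100).
#' @param Io open-pore current, pA.
#' @param poles analysis filter order.
#' @return Switching rate lambda, s^-1.
#' @examples
#' pr <- AnalyteProfile("x", c(72.8, 34.8, 25),
#'                      c(0.4213, 0.5771, 0.0016), 1, 1, 5)
#' calibrateSwitchingRate(pr, 78.9)
#' @export
calibrateSwitchingRate <- function(profile, target_in, cutoff = 100,
                                   Io = 500, poles = 8) {
  stopifnot(is(profile, "AnalyteProfile"), target_in > 0)
  v <- .telegraphVariance(profile, Io)
  if (target_in^2 >= v)
    stop("target I_N exceeds the total level-switching RMS (",
         sprintf("%.1f pA", sqrt(v)), "); unreachable at any rate")
  # integrate the Lorentzian x |H|^2 with the substitution
  # u = atan(2 pi f / lambda): d(band variance) = (2v/pi) |H(f(u))|^2 du,
  # which is smooth and bounded on [0, pi/2) for every lambda
  proto <- .besselPrototype(poles)
  mag2 <- function(f) proto$mag2(f / cutoff * proto$w3)
  bandvar <- function(lam) {
    stats::integrate(function(u) 2 * v / pi *
                       vapply(lam * tan(u) / (2 * pi), mag2, 0),
                     0, pi / 2 - 1e-10, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(l) bandvar(l) - target_in^2,
                 lower = 1e-3, upper = 1e6, tol = 1e-6)$root
}

## ------------------------------------------------------ analyte presets

# common preset machinery: levels in % Io, occupancies, I_N target at 100 Hz
.makeProfile <- function(label, residuals, occ, in_target, tau_off,
                         capture_rate, Io) {
  pr <- AnalyteProfile(label, residuals, occ, switch_rate = 1,
                       tau_off = tau_off, capture_rate = capture_rate)
  pr@switchRate <- calibrateSwitchingRate(pr, in_target, cutoff = 100,
                                          Io = Io)
  pr
}

#' Calibrated analyte presets
#'
#' Generator profiles for the free target protein and its three ligand
#' complexes, with level occupancies as reported for each analyte
#' (free: 4.98/91.25/3.77%; Bak-BH3 complex: 42.13/57.71/0.16%;
#' ABT-737 complex: 13.29/86.66/0.05%), dominant-level residual currents
#' matching the reported blockades (free 65.2%, ABT-737 63.0%,
#' A-1331852 51.1%), and switching rates calibrated by
#' [calibrateSwitchingRate()] to the reported I_N at 100 Hz (free
#' 16.3 pA, Bak-BH3 78.9 pA, ABT-737 28.2 pA, A-1331852 36.3 pA).
#' Dwell and capture times are generator choices at the scale of the
#' recordings (sub-second to second events).
#'
#' @param Io open-pore current, pA (default 500: a 5 nS pore at
#'   +100 mV).
#' @return An [AnalyteProfile-class].
#' @name analytePresets
NULL

#' @rdname analytePresets
#' @export
freeProteinProfile <- function(Io = 500)
  .makeProfile("free", c(72.8, 34.8, 25), c(0.0498, 0.9125, 0.0377),
               in_target = 16.3, tau_off = 0.3, capture_rate = 1 / 0.15,
               Io = Io)

#' @rdname analytePresets
#' @export
bakBH3ComplexProfile <- function(Io = 500)
  .makeProfile("bak-bh3", c(72.8, 34.8, 25), c(0.4213, 0.5771, 0.0016),
               in_target = 78.9, tau_off = 1.0, capture_rate = 1 / 0.2,
               Io = Io)

#' @rdname analytePresets
#' @export
abt737ComplexProfile <- function(Io = 500)
  .makeProfile("abt-737", c(75, 37, 25), c(0.1329, 0.8666, 0.0005),
               in_target = 28.2, tau_off = 0.8, capture_rate = 1 / 0.2,
               Io = Io)

#' @rdname analytePresets
#' @export
a1331852ComplexProfile <- function(Io = 500)
  .makeProfile("a-1331852", c(86.9, 48.9, 30), c(0.1329, 0.8666, 0.0005),
               in_target = 36.3, tau_off = 0.8, capture_rate = 1 / 0.2,
               Io = Io)

## --------------------------------------------------------- noise fields

# band-limited 1/f^alpha noise by spectral synthesis (one-sided PSD
# amp/f^alpha pA^2/Hz), zero mean
.flickerNoise <- function(n, fs, amp, alpha) {
  if (amp <= 0 || n < 4) return(numeric(n))
  m <- n %/% 2
  f <- (1:m) * fs / n
  # half-spectrum with random phases; Hermitian symmetry for a real signal
  mag <- sqrt(amp / f^alpha * fs / 2)   # two-sided density * fs scaling
  re <- stats::rnorm(m); im <- stats::rnorm(m)
  X <- complex(real = mag * re, imaginary = mag * im) / sqrt(2)
  spec <- complex(length.out = n)
  spec[2:(m + 1)] <- X
  spec[n:(n - m + 2)] <- Conj(X[1:(m - 1)])
  if (n %% 2 == 0) spec[m + 1] <- complex(real = sqrt(2) * Re(X[m]))
  Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
}

## ------------------------------------------------------ event train

# one CTMC level path of n samples; returns integer level ids
.ctmcPath <- function(n, occ, lambda, fs) {
  k <- length(occ)
  st <- sample.int(k, 1, prob = occ)
  out <- integer(n); i <- 1L
  if (lambda <= 0 || k == 1) { out[] <- st; return(out) }
  while (i <= n) {
    rate <- lambda * (1 - occ[st])
    d <- if (rate > 0) stats::rexp(1, rate) else Inf
    nd <- max(1L, as.integer(round(d * fs)))
    j <- min(n, i + nd - 1L)
    out[i:j] <- st
    i <- j + 1L
    pr <- occ; pr[st] <- 0
    st <- sample.int(k, 1, prob = pr)
  }
  out
}

#' Generate an annotated synthetic event train
#'
#' Produces a continuous current trace of capture-trap-escape events on
#' an open-pore baseline, with exact ground-truth annotations.
#' Inter-event (open-pore) intervals are exponential with mean
#' 1/capture_rate; event durations are exponential with mean tau_off
#' (optionally truncated below `min_event_s`); within an event the level
#' follows the profile's continuous-time Markov chain, whose stationary
#' distribution equals the configured occupancies. White and flicker
#' noise are added over the whole trace, and an optional hardware
#' low-pass Bessel filter is applied last.
#'
#' @param profile an [AnalyteProfile-class].
#' @param noise a [NoiseModel-class]; `NoiseModel(0)` gives the
#'   noise-free rectangular train.
#' @param Io open-pore current, pA.
#' @param sampling_rate acquisition sampling rate, Hz.
#' @param duration trace duration, s.
#' @param seed RNG seed (optional; forwarded to `set.seed`).
#' @param min_event_s discard-and-redraw threshold for event durations,
#'   s (default 0: plain exponential durations).
#' @param hardware_cutoff optional hardware Bessel cutoff, Hz
#'   (8-pole, causal); NULL for none.
#' @param n_events if non-NULL, continue past `duration` until this many
#'   events have been emitted (duration then sets only a lower bound).
#' @return list with `trace` (an [IonTrace-class]) and `annotation`:
#'   `events` data.frame (`event_id`, `start`, `end` 0-based half-open
#'   sample indices, `label`) and `segments` data.frame (`event_id`,
#'   `start`, `end`, `level`, `ires_pct`).
#' @examples
#' tr <- generateEventTrain(freeProteinProfile(), NoiseModel(0), Io = 500,
#'                          sampling_rate = 1e4, duration = 2, seed = 1)
#' nrow(tr$annotation$events)
#' @export
generateEventTrain <- function(profile, noise = NoiseModel(), Io = 500,
                               sampling_rate = 1e5, duration = 10,
                               seed = NULL, min_event_s = 0,
                               hardware_cutoff = NULL, n_events = NULL) {
  stopifnot(is(profile, "AnalyteProfile"), is(noise, "NoiseModel"),
            duration > 0, Io > 0)
  if (!is.null(hardware_cutoff) && hardware_cutoff >= sampling_rate / 2)
    stop("hardware cutoff must be below Nyquist")
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate
  lev_pA <- profile@levelResidualPct / 100 * Io
  occ <- profile@occupancies

  chunks <- list(); ev_start <- integer(); ev_end <- integer()
  seg_rows <- list()
  pos <- 0L; t_total <- round(duration * fs); nev <- 0L
  repeat {
    gap <- stats::rexp(1, profile@captureRate)
    ng <- max(1L, as.integer(round(gap * fs)))
    chunks[[length(chunks) + 1L]] <- rep(Io, ng)
    pos <- pos + ng
    if (pos >= t_total &&
        (is.null(n_events) || nev >= n_events)) break
    repeat {
      dur <- stats::rexp(1, 1 / profile@tauOff)
      if (dur >= min_event_s) break
    }
    nd <- max(3L, as.integer(round(dur * fs)))
    path <- .ctmcPath(nd, occ, profile@switchRate, fs)
    chunks[[length(chunks) + 1L]] <- lev_pA[path]
    nev <- nev + 1L
    ev_start[nev] <- pos          # 0-based: pos samples precede
    ev_end[nev] <- pos + nd
    r <- rle(path)
    ends <- cumsum(r$lengths)
    seg_rows[[nev]] <- data.frame(
      event_id = nev,
      start = pos + c(0L, ends[-length(ends)]),
      end = pos + ends,
      level = paste0("L", r$values),
      ires_pct = profile@levelResidualPct[r$values])
    pos <- pos + nd
    if (pos >= t_total && (is.null(n_events) || nev >= n_events)) {
      chunks[[length(chunks) + 1L]] <- rep(Io, max(3L, as.integer(0.01 * fs)))
      pos <- pos + max(3L, as.integer(0.01 * fs))
      break
    }
  }
  x <- unlist(chunks, use.names = FALSE)
  n <- length(x)
  if (noise@whiteRms > 0) x <- x + stats::rnorm(n, 0, noise@whiteRms)
  if (noise@flickerAmp > 0)
    x <- x + .flickerNoise(n, fs, noise@flickerAmp, noise@flickerExponent)

  filt <- data.frame(type = character(), poles = integer(),
                     cutoff_hz = numeric())
  if (!is.null(hardware_cutoff)) {
    x <- .besselFilter(x, hardware_cutoff, fs, 8)
    filt <- data.frame(type = "bessel", poles = 8L,
                       cutoff_hz = hardware_cutoff)
  }
  trace <- IonTrace(x, fs, voltage = 100, filter_state = filt,
                    provenance = sprintf("synthetic:%s", profile@label))
  events <- if (nev > 0)
    data.frame(event_id = seq_len(nev), start = ev_start, end = ev_end,
               label = profile@label)
  else
    data.frame(event_id = integer(), start = integer(), end = integer(),
               label = character())
  list(trace = trace,
       annotation = list(events = events,
                         segments = do.call(rbind, seg_rows)))
}

#' Stationary distribution check for a rate matrix
#'
#' Verifies that the stationary distribution of a CTMC rate matrix
#' matches target occupancies; errors beyond tolerance. Exposed so
#' custom rate matrices can be validated before generation.
#'
#' @param Q square rate matrix (rows sum to 0, off-diagonals >= 0).
#' @param occupancies target stationary probabilities.
#' @param tol maximum absolute deviation tolerated.
#' @return Invisibly, the stationary distribution of Q.
#' @export
checkStationary <- function(Q, occupancies, tol = 1e-6) {
  Q <- as.matrix(Q)
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rate matrix rows must sum to 0")
  p <- .statDist(Q)
  if (max(abs(p - occupancies)) > tol)
    stop("stationary distribution of the rate matrix (",
         paste(sprintf("%.4f", p), collapse = ", "),
         ") does not match the configured occupancies")
  invisible(p)
}

## -------------------------------------------------------- titration

#' Generate binomial titration counts from the one-site binding law
#'
#' At ligand concentration X the probability that a trapped-protein event
#' is ligand-bound is \eqn{\min(1, B_{max} X/(K_D + X))}; complexed
#' counts are drawn binomially. A warning is issued when the cap at 1
#' engages (possible when B_max > 1, as fitted saturation levels can
#' be).
#'
#' @param KD dissociation constant, nM (> 0).
#' @param Bmax saturation bound fraction (dimensionless, ~1).
#' @param concentrations ligand concentrations, nM.
#' @param events_per_point total events per concentration.
#' @param seed optional RNG seed.
#' @return A [TitrationSeries-class].
#' @examples
#' generateTitration(19, 1.11, c(1, 5, 20, 100, 500), 300, seed = 1)
#' @export
generateTitration <- function(KD, Bmax, concentrations, events_per_point,
                              seed = NULL) {
  stopifnot(KD > 0, events_per_point > 0, all(concentrations >= 0))
  if (!is.null(seed)) set.seed(seed)
  p <- Bmax * concentrations / (KD + concentrations)
  if (any(p > 1)) {
    warning("binding probability capped at 1 for ",
            sum(p > 1), " concentration(s)")
    p <- pmin(1, p)
  }
  n_comp <- stats::rbinom(length(p), events_per_point, p)
  TitrationSeries(concentrations, n_comp,
                  rep(events_per_point, length(p)))
}

#' Generate a first-order competition time-course
#'
#' Models displacement of a pre-formed complex population by a competing
#' ligand as a first-order exchange: the fraction displaced at time t is
#' \eqn{1 - e^{-kt}}. Event labels are sampled per observation window.
#'
#' @param initial_label population label at t = 0.
#' @param new_label label of the displacing population.
#' @param k displacement rate, s^-1 (>= 0).
#' @param window_times observation window centres, s.
#' @param events_per_window events sampled in each window.
#' @param seed optional RNG seed.
#' @return data.frame with `time_s`, `n_initial`, `n_new`,
#'   `frac_new_pct`.
#' @export
generateCompetitionTimecourse <- function(initial_label, new_label, k,
                                          window_times, events_per_window,
                                          seed = NULL) {
  stopifnot(k >= 0, events_per_window > 0)
  if (!is.null(seed)) set.seed(seed)
  p_new <- 1 - exp(-k * window_times)
  n_new <- stats::rbinom(length(window_times), events_per_window, p_new)
  data.frame(time_s = window_times,
             n_initial = events_per_window - n_new,
             n_new = n_new,
             frac_new_pct = 100 * n_new / events_per_window)
}
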