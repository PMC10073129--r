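## Analog Bessel low-pass prototype + prewarped bilinear transform, applied
## as a cascade of second-order sections. Direct high-order IIR coefficients
## are numerically useless at cutoff/sampling ratios of 1e-3, which is the
## routine regime here (100 Hz analysis filter on a 100 kHz recording), so
## everything stays in SOS form.

# reverse Bessel polynomial coefficients (a_k s^k, k = 0..n) and the poles
# of the -3 dB-normalized analog prototype
.besselPrototype <- function(n) {
  k <- 0:n
  a <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  mag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    Mod(a[1] / sum(a * s^k))^2
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-3, 10),
                       tol = 1e-12)$root
  list(poles = polyroot(a) / w3,
       mag2 = function(w) vapply(w, mag2, 0) ,
       w3 = w3)
}

# |H(j 2 pi f)|^2 of the analog n-pole Bessel low-pass with -3 dB cutoff fc
.besselMag2 <- function(f, fc, poles = 8) {
  proto <- .besselPrototype(poles)
  proto$mag2(f / fc * proto$w3)
}

# digital second-order sections for an n-pole Bessel low-pass
.besselSOS <- function(cutoff, fs, poles = 8) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  wc <- 2 * fs * tan(pi * cutoff / fs)          # prewarped analog cutoff
  p <- .besselPrototype(poles)$poles * wc
  K <- 2 * fs
  sos <- list()
  for (q in p[Im(p) > 1e-9 * Mod(p)]) {         # conjugate pairs, once
    c1 <- -2 * Re(q); c0 <- Mod(q)^2            # s^2 + c1 s + c0
    den0 <- K^2 + c1 * K + c0
    sos[[length(sos) + 1]] <- list(
      b = c0 * c(1, 2, 1) / den0,
      a = c(1, (2 * c0 - 2 * K^2) / den0, (K^2 - c1 * K + c0) / den0))
  }
  for (q in p[abs(Im(p)) <= 1e-9 * Mod(p)]) {   # real pole (odd orders)
    w0 <- -Re(q)
    sos[[length(sos) + 1]] <- list(b = w0 * c(1, 1) / (K + w0),
                                   a = c(1, (w0 - K) / (K + w0)))
  }
  sos
}

# causal forward-only filtering through the SOS cascade
.sosFilter <- function(x, sos) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# filter a bare numeric vector (used internally by the generator and the
# noise chain); causal, zero initial state
.besselFilter <- function(x, cutoff, fs, poles = 8) {
  .sosFilter(x, .besselSOS(cutoff, fs, poles))
}

#' Low-pass Bessel filter a trace
#'
#' Applies a causal (forward-only) digital n-pole Bessel low-pass filter,
#' mimicking the patch-clamp amplifier's hardware filter: unit DC gain,
#' -3 dB at the cutoff, and an essentially constant group delay in the
#' passband (which is what keeps level-dwell boundaries unbiased after
#' filtering). The filter is registered in the trace's `filterState`.
#'
#' @param trace an [IonTrace-class].
#' @param cutoff -3 dB cutoff frequency, Hz; must be below Nyquist.
#' @param poles filter order (default 8, the amplifier standard).
#' @return The filtered [IonTrace-class].
#' @examples
#' tr <- IonTrace(rnorm(5000, 500, 10), sampling_rate = 1e4, voltage = 100)
#' flt <- besselLowpass(tr, 1000)
#' sd(traceCurrent(flt)) < sd(traceCurrent(tr))
#' @export
besselLowpass <- function(trace, cutoff, poles = 8) {
  stopifnot(is(trace, "IonTrace"))
  if (cutoff >= samplingRate(trace) / 2)
    stop("cutoff must be below the Nyquist frequency of the trace")
  y <- .besselFilter(traceCurrent(trace), cutoff, samplingRate(trace), poles)
  fs <- rbind(filterState(trace),
              data.frame(type = "bessel", poles = as.integer(poles),
                         cutoff_hz = cutoff))
  IonTrace(y, samplingRate(trace), appliedVoltage(trace), fs,
           trace@provenance)
}
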