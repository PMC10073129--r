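## Periodogram-based current-noise statistic I_N, with the first-bin
## exclusion and the filter-cutoff dependence analysis.

#' One-sided periodogram of an event segment
#'
#' Plain (unwindowed) periodogram of the mean-removed segment: one-sided
#' PSD in pA^2/Hz on bins of width `effective_rate / n`. Satisfies
#' Parseval exactly: `sum(psd) * binWidth` equals the denominator-n
#' sample variance of the mean-removed samples.
#'
#' @param x event samples, pA (numeric), or an [IonTrace-class] (whole
#'   trace used).
#' @param effective_rate sampling rate of `x`, Hz (taken from the trace
#'   if one is given).
#' @param min_samples minimum segment length (default 64).
#' @return A [NoiseSpectrum-class].
#' @examples
#' sp <- eventPeriodogram(sin(2 * pi * 10 * (0:999) / 1000), 1000)
#' @export
eventPeriodogram <- function(x, effective_rate = NULL, min_samples = 64) {
  if (is(x, "IonTrace")) {
    effective_rate <- samplingRate(x)
    x <- traceCurrent(x)
  }
  if (is.null(effective_rate) || effective_rate <= 0)
    stop("effective_rate must be supplied for numeric input")
  n <- length(x)
  if (n < min_samples)
    stop("segment too short for a periodogram (", n, " < ",
         min_samples, " samples)")
  x <- x - mean(x)
  X <- stats::fft(x)
  kmax <- n %/% 2
  P <- Mod(X[2:(kmax + 1)])^2 * 2 / (n * effective_rate)
  if (n %% 2 == 0) P[kmax] <- P[kmax] / 2      # Nyquist bin is not doubled
  bw <- effective_rate / n
  new("NoiseSpectrum", frequencies = (1:kmax) * bw, psd = P,
      binWidth = bw, nSamples = as.integer(n), excludedBins = integer())
}

#' Integrated current noise I_N of a spectrum
#'
#' \eqn{I_N = \sqrt{\sum_i P_i \, \Delta f}} over retained bins: the RMS
#' of the event's current fluctuations. The DC bin is already absent
#' (mean removal); in addition the first `exclude_leading_bins` non-DC
#' bins are excluded, because edge discontinuities of the finite segment
#' leak into the lowest bins.
#'
#' @param spectrum a [NoiseSpectrum-class].
#' @param exclude_leading_bins number of leading non-DC bins to drop
#'   (default 1).
#' @return I_N in pA (single numeric).
#' @examples
#' sp <- eventPeriodogram(10 * sin(2 * pi * 100 * (0:4095) / 4096), 1)
#' computeIN(sp)  # ~ 10/sqrt(2)
#' @export
computeIN <- function(spectrum, exclude_leading_bins = 1) {
  stopifnot(is(spectrum, "NoiseSpectrum"))
  keep <- seq_along(spectrum@psd)
  if (exclude_leading_bins > 0)
    keep <- keep[-seq_len(min(exclude_leading_bins, length(keep) - 1))]
  sqrt(sum(spectrum@psd[keep] * spectrum@binWidth))
}

#' I_N of an event at several analysis filter cutoffs
#'
#' Re-filters the event's (raw or hardware-filtered) samples with a
#' causal 8-pole Bessel low-pass at each cutoff, trims the filter settle
#' margin, and computes the first-bin-excluded I_N of the remainder.
#' I_N is non-decreasing in the cutoff for any fixed signal.
#'
#' @param event one row of a [detectEvents()] table.
#' @param trace the [IonTrace-class] the event belongs to.
#' @param cutoffs analysis cutoffs, Hz (default 100, 1000, 10000;
#'   cutoffs at or above Nyquist are an error).
#' @param poles filter order (default 8).
#' @param settle_s settle margin trimmed from each end after filtering,
#'   s; default 1/cutoff.
#' @param exclude_leading_bins forwarded to [computeIN()].
#' @return data.frame with `event_id`, `cutoff_hz`, `in_pA`, `n_samples`
#'   (NA I_N where the trimmed segment is shorter than 64 samples).
#' @export
inVsCutoff <- function(event, trace, cutoffs = c(100, 1000, 10000),
                       poles = 8, settle_s = NULL,
                       exclude_leading_bins = 1) {
  stopifnot(is(trace, "IonTrace"))
  fs <- samplingRate(trace)
  if (any(cutoffs >= fs / 2))
    stop("cutoffs must be below the Nyquist frequency")
  x0 <- traceCurrent(trace)[(event$start + 1):event$end]
  out <- lapply(cutoffs, function(fc) {
    st <- if (is.null(settle_s)) 1 / fc else settle_s
    m <- round(st * fs)
    y <- .besselFilter(x0 - x0[1], fc, fs, poles)   # zero-state offset trick
    if (length(y) > 2 * m + 64) {
      y <- y[(m + 1):(length(y) - m)]
      sp <- eventPeriodogram(y, fs)
      data.frame(event_id = event$event_id %||% NA_integer_,
                 cutoff_hz = fc, in_pA = computeIN(sp, exclude_leading_bins),
                 n_samples = length(y))
    } else {
      data.frame(event_id = event$event_id %||% NA_integer_,
                 cutoff_hz = fc, in_pA = NA_real_, n_samples = length(y))
    }
  })
  do.call(rbind, out)
}
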