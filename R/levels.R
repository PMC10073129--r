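## Within-event multi-level segmentation and open-probability statistics.

#' Segment an event into discrete blockade levels
#'
#' Amplitude-histogram idealization of one trapped-protein event: the
#' kernel density of the in-event samples is searched for peaks (shallow
#' valleys merged, at most `max_levels` kept by height); samples are
#' assigned to the peak on their side of the density valleys; runs
#' shorter than `min_level_dwell` are merged into their neighbours.
#' Level labels are ranked by residual current: L1 is the shallowest
#' (highest-current) level.
#'
#' When no multi-peak structure is resolvable the whole event becomes a
#' single L1 segment and the `fallback` attribute is set.
#'
#' @param event one row of a [detectEvents()] table (or a list with
#'   `start`, `end`, `io_local`).
#' @param trace the [IonTrace-class] the event was detected in.
#' @param max_levels maximum number of levels (default 3).
#' @param min_level_dwell minimum level dwell, s (default 5 samples at
#'   the trace rate).
#' @param min_peak_frac minimum density-peak height as a fraction of the
#'   tallest peak (default 0.02); lower it to resolve very rare levels
#'   on clean data.
#' @return data.frame with `event_id`, `start`, `end` (0-based half-open,
#'   absolute trace indices), `level` ("L1".."L3"), `ires_pct`,
#'   `duration_s`; attribute `fallback` TRUE if segmentation degenerated
#'   to a single level.
#' @export
segmentLevels <- function(event, trace, max_levels = 3,
                          min_level_dwell = NULL, min_peak_frac = 0.02) {
  stopifnot(is(trace, "IonTrace"))
  fs <- samplingRate(trace)
  if (is.null(min_level_dwell)) min_level_dwell <- 5 / fs
  a <- event$start; b <- event$end
  x <- traceCurrent(trace)[(a + 1):b]          # 0-based half-open -> R index
  if (length(x) < 3 * max(1, round(min_level_dwell * fs)))
    stop("event too short to segment at this minimum level dwell")
  io <- if (!is.null(event$io_local)) event$io_local else max(x)

  dp <- .densityPeaks(x, min_frac = min_peak_frac)
  pk <- dp$peaks
  if (max_levels == 1) pk <- pk[which.max(dp$dens[pk])]
  if (length(pk) > max_levels)
    pk <- sort(pk[order(dp$dens[pk], decreasing = TRUE)[1:max_levels]])
  fallback <- length(pk) == 1
  if (!fallback) {
    K <- length(pk)
    bnd <- vapply(seq_len(K - 1), function(i) {
      ii <- pk[i]:pk[i + 1]
      dp$grid[ii[which.min(dp$dens[ii])]]
    }, 0)
    lab <- findInterval(x, bnd) + 1L
  } else lab <- rep(1L, length(x))

  # merge runs shorter than the minimum dwell into the preceding run
  r <- rle(lab)
  minn <- max(1L, as.integer(round(min_level_dwell * fs)))
  while (any(r$lengths < minn) && length(r$lengths) > 1) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= minn) break
    r$values[i] <- if (i == 1) r$values[i + 1] else r$values[i - 1]
    r <- rle(inverse.rle(r))
  }
  lab <- inverse.rle(r)

  ids <- sort(unique(lab))
  mu <- vapply(ids, function(k) mean(x[lab == k]), 0)
  rk <- rank(-mu, ties.method = "first")       # highest current -> L1
  lev_of <- stats::setNames(rk, ids)

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    event_id = if (!is.null(event$event_id)) event$event_id else NA_integer_,
    start = a + starts - 1L,
    end = a + ends,
    level = paste0("L", lev_of[as.character(r$values)]),
    ires_pct = 100 * mu[match(r$values, ids)] / io,
    duration_s = r$lengths / fs)
  rownames(out) <- NULL
  attr(out, "fallback") <- fallback
  out
}

#' Cohort open probabilities per level
#'
#' Time-weighted open probability of each level over an event cohort:
#' total time spent in the level divided by total trapped time, in
#' percent (sums to 100), with the cohort mean residual current and mean
#' segment duration per level.
#'
#' @param segments row-bound [segmentLevels()] output over a cohort.
#' @return data.frame with `level`, `open_prob_pct`, `mean_ires_pct`,
#'   `mean_duration_s`, `total_time_s`.
#' @export
openProbabilities <- function(segments) {
  if (nrow(segments) == 0) stop("empty segmentation")
  tt <- tapply(segments$duration_s, segments$level, sum)
  ir <- tapply(segments$ires_pct * segments$duration_s, segments$level,
               sum) / tt
  md <- tapply(segments$duration_s, segments$level, mean)
  out <- data.frame(level = names(tt),
                    open_prob_pct = 100 * as.numeric(tt) / sum(tt),
                    mean_ires_pct = as.numeric(ir),
                    mean_duration_s = as.numeric(md),
                    total_time_s = as.numeric(tt))
  out[order(out$level), , drop = FALSE]
}

#' Residual current per level across voltages
#'
#' Combines per-voltage level statistics and reports, per level, the
#' linear trend of residual current with voltage. Levels absent at a
#' voltage are recorded as absent (NA), not interpolated.
#'
#' @param cohorts named list: names are voltages (mV), values are
#'   [openProbabilities()] tables.
#' @return list with `table` (long data.frame: `voltage_mv`, `level`,
#'   `mean_ires_pct`, `open_prob_pct`) and `trend` (per level: slope
#'   %/mV, and a `direction` of "decreasing"/"increasing"/"flat").
#' @export
levelVoltageTrend <- function(cohorts) {
  if (length(cohorts) < 2) stop("need cohorts at >= 2 voltages")
  volts <- as.numeric(names(cohorts))
  if (anyNA(volts)) stop("cohort names must be voltages in mV")
  long <- do.call(rbind, lapply(seq_along(cohorts), function(i) {
    data.frame(voltage_mv = volts[i], cohorts[[i]][
      c("level", "mean_ires_pct", "open_prob_pct")])
  }))
  levels_all <- sort(unique(long$level))
  trend <- do.call(rbind, lapply(levels_all, function(L) {
    sub <- long[long$level == L, ]
    if (nrow(sub) < 2)
      return(data.frame(level = L, slope_pct_per_mv = NA_real_,
                        direction = "absent"))
    sl <- stats::coef(stats::lm(mean_ires_pct ~ voltage_mv, sub))[[2]]
    dir <- if (abs(sl) < 1e-9) "flat" else
      if (sl < 0) "decreasing" else "increasing"
    data.frame(level = L, slope_pct_per_mv = sl, direction = dir)
  }))
  list(table = long, trend = trend)
}
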