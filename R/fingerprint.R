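## 2D blockade-versus-noise fingerprinting, population models, bound
## fractions, one-site binding fits, competition time-courses.

#' Fingerprint events in the blockade-noise plane
#'
#' One point per event: x = median-current blockade (percent of Io),
#' y = I_N at the analysis cutoff (default 100 Hz, the low-frequency
#' band where level-switching dynamics separate complexes from free
#' protein). Events whose trimmed segment is too short for a
#' periodogram get NA I_N and are dropped with a message.
#'
#' @param events [detectEvents()] table.
#' @param trace the [IonTrace-class] the events belong to.
#' @param cutoff analysis filter cutoff for I_N, Hz.
#' @param reference optional reference cohort fingerprint (a data.frame
#'   from this function): adds `dio_norm`, `in_norm` columns normalized
#'   by the reference's Gaussian-peak blockade and mean I_N.
#' @param wall_time_s optional per-event wall-clock time, s (for
#'   time-course analyses); defaults to the event start time.
#' @param label optional population label column.
#' @return data.frame with `event_id`, `dio_pct`, `in_pA`,
#'   `wall_time_s`, `label` (+ normalized columns if a reference was
#'   given).
#' @export
fingerprintEvents <- function(events, trace, cutoff = 100,
                              reference = NULL, wall_time_s = NULL,
                              label = NA_character_) {
  stopifnot(is(trace, "IonTrace"))
  fs <- samplingRate(trace)
  if (nrow(events) == 0) stop("no events to fingerprint")
  ins <- vapply(seq_len(nrow(events)), function(i) {
    inVsCutoff(events[i, ], trace, cutoffs = cutoff)$in_pA
  }, 0)
  out <- data.frame(event_id = events$event_id,
                    dio_pct = events$blockade_pct,
                    in_pA = ins,
                    wall_time_s = if (is.null(wall_time_s))
                      events$start / fs else wall_time_s,
                    label = label)
  bad <- is.na(out$in_pA)
  if (any(bad)) {
    message(sum(bad), " event(s) too short for I_N at ", cutoff,
            " Hz; dropped")
    out <- out[!bad, , drop = FALSE]
  }
  if (!is.null(reference)) {
    ref_dio <- .gaussHistFit(reference$dio_pct)$mean
    ref_in <- mean(reference$in_pA)
    if (ref_dio <= 0 || ref_in <= 0)
      stop("reference cohort has non-positive normalization constants")
    out$dio_norm <- out$dio_pct / ref_dio
    out$in_norm <- out$in_pA / ref_in
  }
  rownames(out) <- NULL
  out
}

#' Fit a 2D Gaussian mixture population model to fingerprints
#'
#' Models the (blockade, I_N) point cloud as a K-component Gaussian
#' mixture with full covariances; events are assigned by maximum
#' posterior (ties go to the lowest component index).
#'
#' @param points fingerprint data.frame (`dio_pct`, `in_pA`).
#' @param K number of populations.
#' @param seed optional RNG seed (mixture initialization).
#' @return An Mclust-based model list with elements `means` (2 x K),
#'   `covariances` (2 x 2 x K), `weights`, `loglik`, and the fitted
#'   `mclust` object in `fit`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fitPopulations <- function(points, K, seed = NULL) {
  if (nrow(points) < 10 * K)
    stop("need at least 10*K points to fit ", K, " populations")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(points[, c("dio_pct", "in_pA")])
  fit <- mclust::Mclust(X, G = K,
                        modelNames = if (K == 1) "XXX" else "VVV",
                        verbose = FALSE)
  if (is.null(fit)) stop("population mixture fit did not converge")
  list(means = fit$parameters$mean,
       covariances = fit$parameters$variance$sigma,
       weights = fit$parameters$pro,
       loglik = fit$loglik,
       fit = fit)
}

#' @rdname fitPopulations
#' @param model a model from [fitPopulations()].
#' @return `classifyEvents`: the `points` data.frame with a
#'   `population` integer column.
#' @export
classifyEvents <- function(points, model) {
  X <- as.matrix(points[, c("dio_pct", "in_pA")])
  pr <- stats::predict(model$fit, newdata = X)
  points$population <- apply(pr$z, 1, which.max)  # first max: lowest index
  points
}

#' Population fractions over time windows
#'
#' Bins labeled fingerprint points into consecutive time windows and
#' reports the percentage of each population per window (fractions sum
#' to 100 in every non-empty window; empty windows are recorded as
#' missing).
#'
#' @param points data.frame with `wall_time_s` and a label column.
#' @param window window width, s (> 0).
#' @param label_col name of the label column (default "population").
#' @return data.frame with `window_start_s`, `window_end_s`, `n`, one
#'   `frac_<label>_pct` column per population.
#' @export
populationTimecourse <- function(points, window, label_col = "population") {
  if (window <= 0) stop("window must be > 0")
  tmax <- max(points$wall_time_s)
  edges <- seq(0, tmax + window, by = window)
  idx <- findInterval(points$wall_time_s, edges,
                      rightmost.closed = TRUE)
  labs <- sort(unique(points[[label_col]]))
  rows <- lapply(seq_len(length(edges) - 1), function(w) {
    sel <- idx == w
    n <- sum(sel)
    fr <- if (n == 0) rep(NA_real_, length(labs)) else
      vapply(labs, function(L)
        100 * sum(points[[label_col]][sel] == L) / n, 0)
    out <- data.frame(window_start_s = edges[w], window_end_s = edges[w + 1],
                      n = n)
    out[paste0("frac_", labs, "_pct")] <- as.list(fr)
    out
  })
  do.call(rbind, rows)
}

#' Bound fraction from event counts
#'
#' \eqn{F_c = 100 \, N_{comp} / N_{total}} percent.
#'
#' @param n_comp complexed event count.
#' @param n_total total event count (> 0).
#' @return Bound fraction, percent.
#' @examples
#' boundFraction(50, 100)
#' @export
boundFraction <- function(n_comp, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(n_comp > n_total) || any(n_comp < 0))
    stop("need 0 <= n_comp <= n_total")
  100 * n_comp / n_total
}

#' One-site binding fit of a titration series
#'
#' Nonlinear least squares of the one-site law
#' \eqn{Y = B_{max} X / (K_D + X)} to bound fractions (Y = F_c/100)
#' against ligand concentration X. Unweighted by default; an optional
#' binomial-variance weighting is available. 95% confidence intervals
#' come from the fit covariance (t quantiles).
#'
#' @param series a [TitrationSeries-class] or a data.frame with
#'   `conc_nM` and `fc_pct` (and `n_total` if weighting).
#' @param weighted use binomial variance weights (default FALSE).
#' @return list with `KD_nM`, `KD_ci`, `Bmax`, `Bmax_ci`, `residuals`,
#'   and the `fit` object.
#' @examples
#' ts <- generateTitration(19, 1.11, c(1, 2, 5, 10, 20, 50, 100, 500),
#'                         300, seed = 1)
#' fitBinding(ts)$KD_nM
#' @export
fitBinding <- function(series, weighted = FALSE) {
  tb <- if (is(series, "TitrationSeries")) titrationTable(series)
        else as.data.frame(series)
  if (length(unique(tb$conc_nM)) < 4)
    stop("need at least 4 distinct concentrations")
  X <- tb$conc_nM
  Y <- tb$fc_pct / 100
  if (max(Y) - min(Y) < 0.05)
    stop("titration has no curvature (all points saturated or all empty); ",
         "K_D is not identifiable")
  w <- if (weighted) {
    v <- pmax(Y * (1 - Y), 0.25 / tb$n_total) / tb$n_total
    1 / v
  } else rep(1, length(Y))
  st <- list(Bmax = max(Y),
             KD = X[which.min(abs(Y - max(Y) / 2))])
  fit <- minpack.lm::nlsLM(Y ~ Bmax * X / (KD + X), start = st,
                           weights = w,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(0.975, df = length(Y) - 2)
  list(KD_nM = unname(cf[["KD"]]),
       KD_ci = unname(cf[["KD"]] + c(-1, 1) * tq * se[["KD"]]),
       Bmax = unname(cf[["Bmax"]]),
       Bmax_ci = unname(cf[["Bmax"]] + c(-1, 1) * tq * se[["Bmax"]]),
       residuals = unname(stats::resid(fit)),
       fit = fit)
}
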