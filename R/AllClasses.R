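#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- IonTrace

#' IonTrace: a uniformly sampled ionic-current recording
#'
#' Container for one continuous single-channel current trace together with
#' its acquisition metadata. Currents are in pA, sampling rate in Hz, the
#' applied voltage in mV. `filterState` records every low-pass filter the
#' trace has passed through (hardware and analysis refilters), one row per
#' filter, in application order.
#'
#' @slot current numeric vector of current samples, pA.
#' @slot samplingRate sampling rate, Hz.
#' @slot voltage applied voltage, mV.
#' @slot filterState data.frame with columns `type`, `poles`, `cutoff_hz`.
#' @slot provenance free-text origin of the trace.
#'
#' @export
setClass("IonTrace",
  representation(
    current = "numeric",
    samplingRate = "numeric",
    voltage = "numeric",
    filterState = "data.frame",
    provenance = "character"
  ),
  prototype(
    filterState = data.frame(type = character(), poles = integer(),
                             cutoff_hz = numeric()),
    provenance = ""
  )
)

setValidity("IonTrace", function(object) {
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    return("samplingRate must be a single positive number")
  if (anyNA(object@current) || any(!is.finite(object@current)))
    return("current samples must all be finite")
  if (!all(c("type", "poles", "cutoff_hz") %in% names(object@filterState)))
    return("filterState needs columns type, poles, cutoff_hz")
  TRUE
})

#' Construct an IonTrace
#'
#' @param current numeric vector of current samples, pA.
#' @param sampling_rate sampling rate, Hz.
#' @param voltage applied voltage, mV.
#' @param filter_state data.frame of applied filters (`type`, `poles`,
#'   `cutoff_hz`); empty by default.
#' @param provenance character tag describing where the trace came from.
#' @return An [IonTrace-class] object.
#' @examples
#' tr <- IonTrace(rnorm(1000, 500, 5), sampling_rate = 1e5, voltage = 100)
#' samplingRate(tr)
#' @export
IonTrace <- function(current, sampling_rate, voltage = NA_real_,
                     filter_state = NULL, provenance = "") {
  if (is.null(filter_state))
    filter_state <- data.frame(type = character(), poles = integer(),
                               cutoff_hz = numeric())
  new("IonTrace", current = as.numeric(current),
      samplingRate = as.numeric(sampling_rate),
      voltage = as.numeric(voltage), filterState = filter_state,
      provenance = provenance)
}

#' @rdname nanofp-accessors
#' @export
setMethod("traceCurrent", "IonTrace", function(object) object@current)

#' @rdname nanofp-accessors
#' @export
setMethod("samplingRate", "IonTrace", function(object) object@samplingRate)

#' @rdname nanofp-accessors
#' @export
setMethod("appliedVoltage", "IonTrace", function(object) object@voltage)

#' @rdname nanofp-accessors
#' @export
setMethod("filterState", "IonTrace", function(object) object@filterState)

#' @describeIn IonTrace-class number of samples.
#' @param x an IonTrace.
#' @export
setMethod("length", "IonTrace", function(x) length(x@current))

setMethod("show", "IonTrace", function(object) {
  cat(sprintf("IonTrace: %d samples @ %g Hz (%.3f s), voltage %g mV\n",
              length(object@current), object@samplingRate,
              length(object@current) / object@samplingRate, object@voltage))
  if (nrow(object@filterState))
    cat("  filters:",
        paste(sprintf("%s(%d-pole, %g Hz)", object@filterState$type,
                      object@filterState$poles, object@filterState$cutoff_hz),
              collapse = " -> "), "\n")
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

## ---------------------------------------------------- FreeEnergyLandscape

#' FreeEnergyLandscape: potential of mean force along the pore axis
#'
#' The free energy \eqn{\Delta G(z)} of a trapped protein on a strictly
#' increasing grid of axial positions (nm), stored in units of kT. The
#' deterministic force driving the Brownian dynamics is
#' \eqn{F(z) = -d\Delta G/dz}, computed by finite differences.
#'
#' @slot z numeric, axial positions, nm (strictly increasing).
#' @slot deltaG numeric, free energy at each grid point, kT.
#' @slot voltage the voltage label of the landscape, mV.
#'
#' @export
setClass("FreeEnergyLandscape",
  representation(z = "numeric", deltaG = "numeric", voltage = "numeric"))

setValidity("FreeEnergyLandscape", function(object) {
  if (length(object@z) < 2) return("grid needs at least two points")
  if (any(diff(object@z) <= 0)) return("z grid must be strictly increasing")
  if (length(object@z) != length(object@deltaG))
    return("z and deltaG lengths differ")
  if (any(!is.finite(object@deltaG))) return("deltaG must be finite")
  TRUE
})

#' Construct a FreeEnergyLandscape from grid values
#'
#' @param z strictly increasing axial grid, nm.
#' @param deltaG free energy at each grid point, kT.
#' @param voltage voltage label, mV.
#' @return A [FreeEnergyLandscape-class] object.
#' @seealso [buildLandscape()] for the anchored double-well constructor.
#' @export
FreeEnergyLandscape <- function(z, deltaG, voltage = NA_real_) {
  new("FreeEnergyLandscape", z = as.numeric(z), deltaG = as.numeric(deltaG),
      voltage = as.numeric(voltage))
}

#' @rdname nanofp-accessors
#' @export
setMethod("landscapeGrid", "FreeEnergyLandscape", function(object) object@z)

#' @rdname nanofp-accessors
#' @export
setMethod("landscapeEnergy", "FreeEnergyLandscape", function(object) object@deltaG)

setMethod("show", "FreeEnergyLandscape", function(object) {
  cat(sprintf(
    "FreeEnergyLandscape: %d points on [%g, %g] nm, dG range [%.2f, %.2f] kT\n",
    length(object@z), min(object@z), max(object@z),
    min(object@deltaG), max(object@deltaG)))
})

## ------------------------------------------------------------- BDParams

#' BDParams: Brownian dynamics integration parameters
#'
#' Parameters of the overdamped (Ermak-McCammon) position update
#' \eqn{z(t+\Delta t) = z(t) + (D/k_BT) F(z) \Delta t + S}, with S a
#' centred normal increment of variance \eqn{2D\Delta t}. The lower
#' boundary reflects (the constriction excludes the folded protein); the
#' upper boundary either absorbs (escape to the cis side terminates the
#' trajectory) or reflects, for equilibrium studies.
#'
#' @slot diffusion protein diffusion coefficient, nm^2/us.
#' @slot dt integration time step, us.
#' @slot zMin reflecting lower boundary, nm.
#' @slot zMax upper boundary, nm.
#' @slot zMaxBoundary `"absorbing"` or `"reflecting"`.
#'
#' @export
setClass("BDParams",
  representation(diffusion = "numeric", dt = "numeric", zMin = "numeric",
                 zMax = "numeric", zMaxBoundary = "character"),
  prototype(diffusion = 10, dt = 1e-4, zMin = 2, zMax = 13,
            zMaxBoundary = "absorbing"))

setValidity("BDParams", function(object) {
  if (object@diffusion <= 0) return("diffusion must be > 0")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@zMin >= object@zMax) return("zMin must be < zMax")
  if (!object@zMaxBoundary %in% c("absorbing", "reflecting"))
    return("zMaxBoundary must be 'absorbing' or 'reflecting'")
  TRUE
})

#' Construct BDParams
#'
#' Defaults are the protein-in-pore conditions: D = 10 nm^2/us,
#' dt = 1e-4 us, reflecting wall at z = 2 nm and absorbing escape
#' boundary at z = 13 nm.
#'
#' @param diffusion diffusion coefficient, nm^2/us.
#' @param dt time step, us.
#' @param z_min reflecting lower boundary, nm.
#' @param z_max upper boundary, nm.
#' @param z_max_boundary `"absorbing"` (default) or `"reflecting"`.
#' @return A [BDParams-class] object.
#' @export
BDParams <- function(diffusion = 10, dt = 1e-4, z_min = 2, z_max = 13,
                     z_max_boundary = c("absorbing", "reflecting")) {
  new("BDParams", diffusion = diffusion, dt = dt, zMin = z_min, zMax = z_max,
      zMaxBoundary = match.arg(z_max_boundary))
}

## ------------------------------------------------------------ CurrentMap

#' CurrentMap: axial position to residual current
#'
#' Monotone map from the trapped protein's axial position z (nm) to the
#' residual current as a percent of the open-pore current. Deeper
#' positions (small z, closer to the constriction) block more current.
#' Between anchors the residual fraction is interpolated linearly and
#' clamped outside the anchored range; positions after escape emit the
#' open-pore current.
#'
#' @slot z anchor positions, nm.
#' @slot residualPct residual current at each anchor, percent of Io.
#' @slot openPoreCurrent open-pore current Io, pA.
#'
#' @export
setClass("CurrentMap",
  representation(z = "numeric", residualPct = "numeric",
                 openPoreCurrent = "numeric"))

setValidity("CurrentMap", function(object) {
  if (any(diff(object@z) <= 0)) return("anchor z must be strictly increasing")
  if (any(object@residualPct < 0 | object@residualPct > 100))
    return("residual fractions must lie in [0, 100]")
  if (any(diff(object@residualPct) < 0))
    return("map must be monotone non-decreasing in z")
  if (object@openPoreCurrent <= 0) return("open-pore current must be > 0")
  TRUE
})

#' Default position-to-current map
#'
#' Anchors: 35% residual current at z = 4 nm (the deep residence site at
#' +100 mV minus measurement rounding: 34.8% so that the dominant-level
#' blockade is 65.2%), 72.8% at z = 10 nm (the ~38 percentage-point
#' difference between the two residence sites), and 25% at z = 2.5 nm for
#' the deepest, rarely visited site.
#'
#' @param Io open-pore current, pA.
#' @return A [CurrentMap-class] object.
#' @export
defaultCurrentMap <- function(Io = 500) {
  new("CurrentMap", z = c(2.5, 4, 10), residualPct = c(25, 34.8, 72.8),
      openPoreCurrent = Io)
}

#' Construct a CurrentMap
#'
#' @param z strictly increasing anchor positions, nm.
#' @param residual_pct residual current at each anchor, percent of Io
#'   (monotone non-decreasing).
#' @param Io open-pore current, pA.
#' @return A [CurrentMap-class] object.
#' @export
CurrentMap <- function(z, residual_pct, Io = 500) {
  new("CurrentMap", z = as.numeric(z), residualPct = as.numeric(residual_pct),
      openPoreCurrent = Io)
}

## ------------------------------------------------------------ NoiseModel

#' NoiseModel: additive instrument/membrane noise
#'
#' White (thermal/amplifier) noise given as RMS at the full acquisition
#' bandwidth, plus an optional flicker (1/f^alpha) component whose
#' one-sided PSD is `flickerAmp / f^alpha` (pA^2/Hz with f in Hz).
#'
#' @slot whiteRms white-noise RMS at acquisition bandwidth, pA.
#' @slot flickerAmp flicker PSD scale, pA^2 Hz^(alpha-1).
#' @slot flickerExponent flicker exponent alpha, in [0.5, 2].
#'
#' @export
setClass("NoiseModel",
  representation(whiteRms = "numeric", flickerAmp = "numeric",
                 flickerExponent = "numeric"),
  prototype(whiteRms = 10, flickerAmp = 0, flickerExponent = 1))

setValidity("NoiseModel", function(object) {
  if (object@whiteRms < 0) return("whiteRms must be >= 0")
  if (object@flickerAmp < 0) return("flickerAmp must be >= 0")
  if (object@flickerExponent < 0.5 || object@flickerExponent > 2)
    return("flickerExponent must lie in [0.5, 2]")
  TRUE
})

#' Construct a NoiseModel
#'
#' @param white_rms white-noise RMS at the acquisition bandwidth, pA.
#'   Default 10 pA (2 percent of a 500 pA open-pore current).
#' @param flicker_amp one-sided flicker PSD scale at 1 Hz, pA^2/Hz.
#' @param flicker_exponent flicker exponent, default 1.
#' @return A [NoiseModel-class] object.
#' @export
NoiseModel <- function(white_rms = 10, flicker_amp = 0, flicker_exponent = 1) {
  new("NoiseModel", whiteRms = white_rms, flickerAmp = flicker_amp,
      flickerExponent = flicker_exponent)
}

## --------------------------------------------------------- AnalyteProfile

#' AnalyteProfile: generator profile of one analyte species
#'
#' Describes the capture-trap-escape statistics of one analyte (free
#' protein or a protein-ligand complex): the discrete blockade levels
#' L1..L3 (residual current, percent of Io, decreasing: L1 shallowest),
#' their stationary occupancies, the level-switching rate of the
#' continuous-time Markov chain, and the capture/escape kinetics.
#'
#' Level switching uses the "jump-to-stationary" chain
#' \eqn{Q = \lambda(\Pi - I)} whose rows of \eqn{\Pi} equal the
#' occupancy vector, so the stationary distribution equals the
#' configured occupancies for every \eqn{\lambda > 0} and the current
#' autocovariance is exactly a single Lorentzian with corner
#' \eqn{\lambda/2\pi} -- which makes the noise calibration in
#' [calibrateSwitchingRate()] closed-form.
#'
#' @slot label analyte name.
#' @slot levelResidualPct residual current per level, percent of Io,
#'   strictly decreasing (L1, L2, L3, ...).
#' @slot occupancies stationary level occupancies, sum to 1.
#' @slot switchRate CTMC jump rate lambda, s^-1.
#' @slot tauOff mean event dwell time, s.
#' @slot captureRate capture rate 1/tau_on, s^-1.
#'
#' @export
setClass("AnalyteProfile",
  representation(label = "character", levelResidualPct = "numeric",
                 occupancies = "numeric", switchRate = "numeric",
                 tauOff = "numeric", captureRate = "numeric"))

setValidity("AnalyteProfile", function(object) {
  if (abs(sum(object@occupancies) - 1) > 1e-9)
    return("occupancies must sum to 1")
  if (any(object@occupancies < 0)) return("occupancies must be >= 0")
  if (length(object@occupancies) != length(object@levelResidualPct))
    return("one occupancy per level required")
  if (any(diff(object@levelResidualPct) >= 0))
    return("level residuals must be strictly decreasing (L1 shallowest)")
  if (object@switchRate < 0 || object@tauOff <= 0 || object@captureRate <= 0)
    return("rates must be positive (switchRate >= 0)")
  TRUE
})

#' Construct an AnalyteProfile
#'
#' @param label analyte name.
#' @param level_residual_pct residual current per level (percent of Io),
#'   strictly decreasing; names L1, L2, ... are implied by position.
#' @param occupancies stationary occupancies (sum to 1), same length.
#' @param switch_rate CTMC jump rate lambda, s^-1.
#' @param tau_off mean trapped dwell time, s.
#' @param capture_rate capture rate 1/tau_on, s^-1.
#' @return An [AnalyteProfile-class] object.
#' @seealso [freeProteinProfile()], [bakBH3ComplexProfile()],
#'   [abt737ComplexProfile()], [a1331852ComplexProfile()] for the
#'   calibrated presets, and [calibrateSwitchingRate()].
#' @export
AnalyteProfile <- function(label, level_residual_pct, occupancies,
                           switch_rate, tau_off, capture_rate) {
  new("AnalyteProfile", label = label,
      levelResidualPct = as.numeric(level_residual_pct),
      occupancies = as.numeric(occupancies), switchRate = switch_rate,
      tauOff = tau_off, captureRate = capture_rate)
}

#' @rdname nanofp-accessors
#' @export
setMethod("levelResiduals", "AnalyteProfile", function(object) {
  stats::setNames(object@levelResidualPct,
                  paste0("L", seq_along(object@levelResidualPct)))
})

#' @rdname nanofp-accessors
#' @export
setMethod("levelOccupancies", "AnalyteProfile", function(object) {
  stats::setNames(object@occupancies,
                  paste0("L", seq_along(object@occupancies)))
})

setMethod("show", "AnalyteProfile", function(object) {
  cat(sprintf("AnalyteProfile '%s': %d levels\n", object@label,
              length(object@occupancies)))
  cat("  I_res (% Io):", paste(sprintf("%.1f", object@levelResidualPct),
                               collapse = " / "), "\n")
  cat("  occupancy  :", paste(sprintf("%.2f%%", 100 * object@occupancies),
                              collapse = " / "), "\n")
  cat(sprintf("  lambda = %.0f /s, tau_off = %g s, capture rate = %g /s\n",
              object@switchRate, object@tauOff, object@captureRate))
})

## --------------------------------------------------------- NoiseSpectrum

#' NoiseSpectrum: one-sided periodogram of an event segment
#'
#' One-sided power spectral density of a mean-removed event segment in
#' pA^2/Hz, with bin width `effective_rate / n`. Satisfies the Parseval
#' identity: `sum(psd) * binWidth` equals the (denominator-n) sample
#' variance of the mean-removed segment.
#'
#' @slot frequencies bin centre frequencies, Hz (excluding DC).
#' @slot psd one-sided PSD per bin, pA^2/Hz.
#' @slot binWidth frequency bin width, Hz.
#' @slot nSamples number of time-domain samples.
#' @slot excludedBins indices of bins excluded from I_N integration.
#'
#' @export
setClass("NoiseSpectrum",
  representation(frequencies = "numeric", psd = "numeric",
                 binWidth = "numeric", nSamples = "integer",
                 excludedBins = "integer"))

setValidity("NoiseSpectrum", function(object) {
  if (length(object@frequencies) != length(object@psd))
    return("frequencies and psd lengths differ")
  if (any(object@psd < 0)) return("psd must be non-negative")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  TRUE
})

setMethod("show", "NoiseSpectrum", function(object) {
  cat(sprintf(
    "NoiseSpectrum: %d bins, width %.3g Hz, total power %.4g pA^2\n",
    length(object@psd), object@binWidth, sum(object@psd) * object@binWidth))
})

#' @rdname nanofp-accessors
#' @export
setMethod("psdFrequencies", "NoiseSpectrum", function(object) object@frequencies)

#' @rdname nanofp-accessors
#' @export
setMethod("psdValues", "NoiseSpectrum", function(object) object@psd)

## -------------------------------------------------------- TitrationSeries

#' TitrationSeries: complexed/total event counts per ligand concentration
#'
#' Per-concentration event counts from a ligand titration: at ligand
#' concentration X (nM), `n_comp` of `n_total` trapped-protein events are
#' classified as ligand-bound, giving the bound fraction
#' F_c = 100 n_comp / n_total, the input of the one-site binding fit.
#'
#' @slot table data.frame with columns `conc_nM`, `n_comp`, `n_total`,
#'   `fc_pct`.
#'
#' @export
setClass("TitrationSeries", representation(table = "data.frame"))

setValidity("TitrationSeries", function(object) {
  tb <- object@table
  need <- c("conc_nM", "n_comp", "n_total", "fc_pct")
  if (!all(need %in% names(tb)))
    return(paste("table needs columns", paste(need, collapse = ", ")))
  if (any(tb$n_comp < 0 | tb$n_comp > tb$n_total))
    return("need 0 <= n_comp <= n_total")
  if (any(abs(tb$fc_pct - 100 * tb$n_comp / tb$n_total) > 1e-8))
    return("fc_pct must equal 100 * n_comp / n_total")
  TRUE
})

#' Construct a TitrationSeries
#'
#' @param conc_nM ligand concentrations, nM.
#' @param n_comp complexed event counts.
#' @param n_total total event counts.
#' @return A [TitrationSeries-class] object.
#' @export
TitrationSeries <- function(conc_nM, n_comp, n_total) {
  new("TitrationSeries",
      table = data.frame(conc_nM = as.numeric(conc_nM),
                         n_comp = as.integer(n_comp),
                         n_total = as.integer(n_total),
                         fc_pct = 100 * n_comp / n_total))
}

#' @rdname nanofp-accessors
#' @export
setMethod("titrationTable", "TitrationSeries", function(object) object@table)

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d concentrations, %d--%d events/point\n",
              nrow(object@table), min(object@table$n_total),
              max(object@table$n_total)))
})

## ----------------------------------------------------- PoreSpec/IonConditions

#' PoreSpec: funnel pore geometry
#'
#' Geometry of a funnel-shaped pore: channel length and the diameters of
#' the wide cis entry, the narrow trans exit and the constriction, all in
#' nm. Defaults are the C8 pore: 18 nm long, 10 nm cis entry, 2.7 nm
#' trans exit, 1.9 nm constriction.
#'
#' @slot symmetry symmetry label ("C8", "C9" or "C10").
#' @slot lengthL channel length, nm.
#' @slot dCisEntry cis entry diameter, nm.
#' @slot dTransExit trans exit diameter, nm.
#' @slot dConstriction constriction diameter, nm.
#'
#' @export
setClass("PoreSpec",
  representation(symmetry = "character", lengthL = "numeric",
                 dCisEntry = "numeric", dTransExit = "numeric",
                 dConstriction = "numeric"),
  prototype(symmetry = "C8", lengthL = 18, dCisEntry = 10,
            dTransExit = 2.7, dConstriction = 1.9))

setValidity("PoreSpec", function(object) {
  dims <- c(object@lengthL, object@dCisEntry, object@dTransExit,
            object@dConstriction)
  if (any(dims <= 0)) return("all lengths must be > 0")
  if (object@dConstriction > object@dCisEntry)
    return("constriction cannot be wider than the cis entry")
  TRUE
})

#' Construct a PoreSpec
#'
#' @param symmetry symmetry label, e.g. "C8".
#' @param length_L channel length, nm.
#' @param d_cis_entry cis entry diameter, nm.
#' @param d_trans_exit trans exit diameter, nm.
#' @param d_constriction constriction diameter, nm.
#' @return A [PoreSpec-class] object. With no arguments, the C8 pore.
#' @export
PoreSpec <- function(symmetry = "C8", length_L = 18, d_cis_entry = 10,
                     d_trans_exit = 2.7, d_constriction = 1.9) {
  new("PoreSpec", symmetry = symmetry, lengthL = length_L,
      dCisEntry = d_cis_entry, dTransExit = d_trans_exit,
      dConstriction = d_constriction)
}

#' IonConditions: electrolyte conditions for selectivity calculations
#'
#' Salt concentrations and mean ion activity coefficients on both sides
#' of the membrane, temperature and (optionally) the bulk solution
#' conductivity. Defaults are the asymmetric reversal-potential
#' condition: 0.5 M KCl cis (activity coefficient 0.649), 2 M KCl trans
#' (0.573), 25 C.
#'
#' @slot cisMolar cis KCl concentration, mol/L.
#' @slot transMolar trans KCl concentration, mol/L.
#' @slot cisActivityCoeff mean ion activity coefficient, cis.
#' @slot transActivityCoeff mean ion activity coefficient, trans.
#' @slot temperature temperature, K.
#' @slot sigmaS solution conductivity, S/m (NA if not used).
#'
#' @export
setClass("IonConditions",
  representation(cisMolar = "numeric", transMolar = "numeric",
                 cisActivityCoeff = "numeric", transActivityCoeff = "numeric",
                 temperature = "numeric", sigmaS = "numeric"),
  prototype(cisMolar = 0.5, transMolar = 2, cisActivityCoeff = 0.649,
            transActivityCoeff = 0.573, temperature = 298.15,
            sigmaS = NA_real_))

setValidity("IonConditions", function(object) {
  if (object@cisMolar <= 0 || object@transMolar <= 0)
    return("molarities must be > 0")
  co <- c(object@cisActivityCoeff, object@transActivityCoeff)
  if (any(co <= 0 | co > 1))
    return("activity coefficients must lie in (0, 1]")
  if (object@temperature <= 0) return("temperature must be > 0")
  TRUE
})

#' Construct IonConditions
#'
#' @param cis_molar cis salt concentration, mol/L.
#' @param trans_molar trans salt concentration, mol/L.
#' @param cis_activity_coeff mean ion activity coefficient, cis side.
#' @param trans_activity_coeff mean ion activity coefficient, trans side.
#' @param temperature temperature, K (default 298.15).
#' @param sigma_s solution conductivity, S/m (used by
#'   [funnelConductance()]).
#' @return An [IonConditions-class] object.
#' @export
IonConditions <- function(cis_molar = 0.5, trans_molar = 2,
                          cis_activity_coeff = 0.649,
                          trans_activity_coeff = 0.573,
                          temperature = 298.15, sigma_s = NA_real_) {
  new("IonConditions", cisMolar = cis_molar, transMolar = trans_molar,
      cisActivityCoeff = cis_activity_coeff,
      transActivityCoeff = trans_activity_coeff,
      temperature = temperature, sigmaS = sigma_s)
}
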