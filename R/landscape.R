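## Free-energy landscape construction and the 1D Brownian dynamics engine.

# kcal/mol -> kT at 298.15 K (kT = 0.592487 kcal/mol)
.KT_PER_KCALMOL <- 1.688

# C1 smoothstep, s in [0, 1]
.smoothstep <- function(s) s * s * (3 - 2 * s)

#' Build a double-well free-energy landscape through anchor points
#'
#' Constructs a smooth free-energy curve \eqn{\Delta G(z)} on a uniform
#' grid over the pore axis that (i) passes exactly through the supplied
#' anchor (well) points, (ii) is flat outside the outermost anchors
#' (clamped; the simulator's boundaries take over there), and (iii) has a
#' single smooth barrier between the two deepest anchors. Between
#' adjacent anchors the base curve is a C1 smoothstep; the barrier is a
#' \eqn{\sin^2} bump of amplitude `barrier_height` (kT) above the base
#' curve, vanishing with zero slope at both anchors, so anchor values are
#' reproduced exactly.
#'
#' @param anchors data.frame/matrix with columns `z` (nm) and `deltaG`;
#'   at least two rows, all z inside `z_range`.
#' @param voltage voltage label of the landscape, mV.
#' @param barrier_height bump amplitude between the two deepest wells, kT.
#' @param unit unit of the anchor `deltaG` values: `"kcal/mol"` (default;
#'   converted at 1 kcal/mol = 1.688 kT, i.e. 25 C) or `"kT"`.
#' @param z_range axial domain, nm (default c(2, 13): constriction-side
#'   wall to the escape boundary).
#' @param dz grid spacing, nm.
#' @return A [FreeEnergyLandscape-class]; `deltaG` in kT.
#' @examples
#' fl <- buildLandscape(data.frame(z = c(4, 10), deltaG = c(-22.81, -10.05)))
#' dG <- landscapeEnergy(fl) / 1.688  # back to kcal/mol
#' dG[landscapeGrid(fl) == 4] - dG[landscapeGrid(fl) == 10]  # -12.76
#' @export
buildLandscape <- function(anchors, voltage = 100, barrier_height = 3,
                           unit = c("kcal/mol", "kT"), z_range = c(2, 13),
                           dz = 0.01) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("z", "deltaG") %in% names(anchors)))
  if (nrow(anchors) < 2) stop("need at least two anchors")
  if (any(anchors$z < z_range[1] | anchors$z > z_range[2]))
    stop("anchors must lie inside the z range")
  unit <- match.arg(unit)
  g <- if (unit == "kcal/mol") anchors$deltaG * .KT_PER_KCALMOL
       else anchors$deltaG
  o <- order(anchors$z)
  az <- anchors$z[o]; ag <- g[o]

  z <- seq(z_range[1], z_range[2], by = dz)
  # base: clamped outside, smoothstep between adjacent anchors
  base <- numeric(length(z))
  base[z <= az[1]] <- ag[1]
  base[z >= az[length(az)]] <- ag[length(ag)]
  for (i in seq_len(length(az) - 1)) {
    sel <- z > az[i] & z < az[i + 1]
    s <- (z[sel] - az[i]) / (az[i + 1] - az[i])
    base[sel] <- ag[i] + (ag[i + 1] - ag[i]) * .smoothstep(s)
  }
  # single barrier between the two deepest anchors
  iw <- order(ag)[1:2]
  i1 <- min(iw); i2 <- max(iw)
  sel <- z > az[i1] & z < az[i2]
  s <- (z[sel] - az[i1]) / (az[i2] - az[i1])
  bump <- numeric(length(z))
  bump[sel] <- barrier_height * sin(pi * s)^2
  FreeEnergyLandscape(z, base + bump, voltage)
}

#' Deterministic force of a landscape
#'
#' Central-difference numerical derivative \eqn{F(z) = -d\Delta G/dz} on
#' the landscape grid, in kT/nm (one-sided at the grid ends).
#'
#' @param landscape a [FreeEnergyLandscape-class].
#' @return Numeric vector of forces, one per grid point.
#' @export
landscapeForce <- function(landscape) {
  stopifnot(is(landscape, "FreeEnergyLandscape"))
  z <- landscape@z; g <- landscape@deltaG
  n <- length(z)
  f <- numeric(n)
  f[2:(n - 1)] <- -(g[3:n] - g[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
  f[1] <- -(g[2] - g[1]) / (z[2] - z[1])
  f[n] <- -(g[n] - g[n - 1]) / (z[n] - z[n - 1])
  f
}

#' Simulate overdamped Brownian dynamics on a landscape
#'
#' Integrates the Ermak-McCammon update
#' \eqn{z(t+\Delta t) = z(t) + (D/k_BT)F(z)\Delta t + S}, where S is a
#' centred normal increment of variance \eqn{2D\Delta t}. The lower
#' boundary reflects; the upper boundary absorbs (trajectory terminates:
#' the protein escapes to the cis side) or reflects, per `params`.
#'
#' Uses R's RNG: call `set.seed()` for reproducible paths.
#'
#' @param landscape a [FreeEnergyLandscape-class] (energies in kT).
#' @param params a [BDParams-class].
#' @param n_steps number of time steps.
#' @param z0 initial position, nm (default: grid midpoint).
#' @param thin keep every `thin`-th sample (default 1 = full path).
#' @return list with `z` (positions, nm, starting at z0), `escaped`
#'   (logical), `steps` (steps actually integrated), `dt_us` (= params dt
#'   times thin, sampling interval of `z`).
#' @examples
#' flat <- FreeEnergyLandscape(seq(0, 100, 0.5), rep(0, 201))
#' set.seed(1)
#' path <- simulateBD(flat, BDParams(z_min = 0, z_max = 100), 1000, z0 = 50)
#' @export
simulateBD <- function(landscape, params = BDParams(), n_steps, z0 = NULL,
                       thin = 1L) {
  stopifnot(is(landscape, "FreeEnergyLandscape"), is(params, "BDParams"))
  z <- landscape@z
  if (is.null(z0)) z0 <- mean(range(z))
  if (z0 < params@zMin || z0 > params@zMax)
    stop("initial position outside [z_min, z_max]")
  f <- landscapeForce(landscape)
  # stability: one drift step must not exceed the grid span
  drift_max <- max(abs(f)) * params@diffusion * params@dt
  if (drift_max > diff(range(z)))
    stop("time step too large: drift per step exceeds the grid span")
  res <- .bdCore(z, f, z0, params@diffusion, params@dt, params@zMin,
                 params@zMax, params@zMaxBoundary == "absorbing",
                 as.integer(n_steps), as.integer(thin))
  res$dt_us <- params@dt * thin
  res
}
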