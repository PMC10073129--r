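## Closed-form pore biophysics: funnel conductance, GHK ion selectivity,
## ion flux to electrical current.

# physical constants (SI)
.const <- list(
  e = 1.602176634e-19,    # elementary charge, C
  FARADAY = 96485.33212,  # C/mol
  RGAS = 8.314462618      # J/mol/K
)

#' Open conductance of a funnel-shaped pore
#'
#' Conductance of a conical (funnel) channel of length L with entry and
#' exit diameters d_in and d_out in a solution of conductivity sigma_s:
#' \deqn{G = 1/R, \quad R = \frac{4}{\sigma_s \pi} \frac{L}{d_{in} d_{out}}.}
#' With d_in = d_out = d this reduces to the uniform cylinder formula
#' \eqn{G = \sigma_s \pi d^2 / (4L)}. Which two diameters of the funnel
#' stand for d_in/d_out is an explicit choice (default: cis entry and
#' constriction).
#'
#' @param pore a [PoreSpec-class].
#' @param conditions an [IonConditions-class] carrying `sigma_s` (S/m), or
#'   a number interpreted as sigma_s directly.
#' @param d_in,d_out which pore diameter to use for the entry/exit term:
#'   one of `"cis_entry"`, `"constriction"`, `"trans_exit"`.
#' @return Conductance in nS.
#' @examples
#' funnelConductance(PoreSpec(), 10.5)  # ~8.70 nS
#' @export
funnelConductance <- function(pore, conditions,
                              d_in = c("cis_entry", "constriction",
                                       "trans_exit"),
                              d_out = c("constriction", "cis_entry",
                                        "trans_exit")) {
  stopifnot(is(pore, "PoreSpec"))
  sigma_s <- if (is(conditions, "IonConditions")) conditions@sigmaS
             else as.numeric(conditions)
  if (!is.finite(sigma_s) || sigma_s <= 0)
    stop("solution conductivity sigma_s must be a positive number")
  pick <- function(which) switch(match.arg(which, c("cis_entry",
                                                    "constriction",
                                                    "trans_exit")),
    cis_entry = pore@dCisEntry,
    constriction = pore@dConstriction,
    trans_exit = pore@dTransExit)
  din <- pick(d_in[1]); dout <- pick(d_out[1])
  if (din <= 0 || dout <= 0 || pore@lengthL <= 0)
    stop("pore geometry must be positive")
  # sigma_s [S/m] * d [nm] * d [nm] / L [nm] -> S * nm/m = nS
  sigma_s * pi * din * dout / (4 * pore@lengthL)
}

#' Ion selectivity from the reversal potential (GHK)
#'
#' Cation/anion permeability ratio of a pore from its reversal potential
#' V_r under asymmetric salt, by the Goldman-Hodgkin-Katz equation for a
#' 1:1 electrolyte (K+ / Cl-):
#' \deqn{\frac{P_{K^+}}{P_{Cl^-}} =
#'   \frac{[a_{Cl}]_{cis} - [a_{Cl}]_{trans} e^{V_r F/RT}}
#'        {[a_{K}]_{cis} e^{V_r F/RT} - [a_{K}]_{trans}}}
#' with ion activities a = activity coefficient x molarity on each side.
#' Sign convention: the working electrode is on the cis side and V_r is
#' the applied (cis) voltage at which the current vanishes.
#'
#' @param conditions an [IonConditions-class]; the default is the
#'   asymmetric measurement condition (cis 0.5 M KCl, trans 2 M KCl).
#' @param Vr reversal potential, mV.
#' @return A list with elements `reversal_potential_mV` and
#'   `permeability_ratio` (P_K+/P_Cl-).
#' @examples
#' ghkSelectivity(IonConditions(), Vr = 11.7)$permeability_ratio  # ~2.34
#' ghkSelectivity(IonConditions(), Vr = 0)$permeability_ratio     # 1
#' @export
ghkSelectivity <- function(conditions = IonConditions(), Vr) {
  stopifnot(is(conditions, "IonConditions"))
  aK_cis <- conditions@cisActivityCoeff * conditions@cisMolar
  aK_trans <- conditions@transActivityCoeff * conditions@transMolar
  aCl_cis <- aK_cis; aCl_trans <- aK_trans   # 1:1 electrolyte
  rtf <- .const$RGAS * conditions@temperature / .const$FARADAY * 1000  # mV
  ex <- exp(Vr / rtf)
  if (!is.finite(ex)) stop("Vr*F/RT is not finite")
  den <- aK_cis * ex - aK_trans
  if (abs(den) < 1e-12 * max(aK_cis, aK_trans))
    stop("Vr equals the K+ Nernst potential: permeability ratio is singular")
  ratio <- (aCl_cis - aCl_trans * ex) / den
  if (ratio <= 0)
    warning("non-positive permeability ratio; Vr outside the physical range")
  list(reversal_potential_mV = Vr, permeability_ratio = ratio)
}

#' Convert an ion crossing rate to electrical current
#'
#' A steady crossing rate of r ions/ns carrying |z| elementary charges is
#' a current of r |z| e, i.e. 160.218 pA per ns^-1 for monovalent ions.
#'
#' @param crossing_rate ion crossings per nanosecond (>= 0).
#' @param valence integer ion charge (sign ignored; magnitude used).
#' @return Current magnitude in pA.
#' @examples
#' fluxToCurrent(1.03)  # ~165 pA
#' @export
fluxToCurrent <- function(crossing_rate, valence = 1L) {
  if (any(crossing_rate < 0)) stop("crossing_rate must be >= 0")
  # ions/ns * C -> 1e9 ions/s * C = 1e9 A scale; in pA: * 1e12 / 1e-9
  crossing_rate * abs(valence) * .const$e * 1e21
}
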