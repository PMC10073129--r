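---
title: "Models, calibration and design choices in nanofp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in nanofp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanofp)
```

# What is being modelled

A large funnel-shaped protein nanopore (the YaxAB toxin pore and its
relatives) traps single folded proteins by electro-osmotic flow. While
trapped, the protein oscillates between residence sites along the pore
axis; each site blocks a different fraction of the ionic current, so one
capture–trap–escape event carries a ladder of discrete blockade levels
(L1 shallowest, L3 deepest). Ligand binding changes two things that this
package quantifies:

* the **distribution of level occupancies** — e.g. the free protein
  spends >90 % of its trapped time in the middle level, while a
  peptide-bound complex splits its time almost evenly between the two
  shallower levels — and
* the **timescale of level switching**, which sets how much fluctuation
  power sits below 100 Hz and therefore the event's low-frequency
  current noise I_N.

The analysis chain (detection → level segmentation → periodogram I_N →
2D fingerprinting → titration fits) never sees the generator's ground
truth; the generator exists so that every analysis stage can be validated
against exact annotations and closed-form expectations.

# The physical generator

## Brownian dynamics

The trapped protein's axial coordinate follows the overdamped
(Ermak–McCammon) update

$$z(t+\Delta t) = z(t) + \frac{D}{k_BT}F(z)\,\Delta t + S,\qquad
  S \sim \mathcal N(0,\ 2D\Delta t),$$

with $F(z) = -\,d\Delta G/dz$ computed by central differences on the
landscape grid. Defaults: $D = 10\ \mathrm{nm^2/\mu s}$ (a folded
~20 kDa protein in a confined channel), $\Delta t = 10^{-4}\ \mu s$,
domain $z \in [2, 13]$ nm with a reflecting wall at 2 nm (the
constriction excludes the folded protein) and an absorbing boundary at
13 nm (escape to the *cis* side ends the event; a reflecting option
exists for equilibrium studies). The phrase "a normal increment of width
$2D\Delta t$" is read as *variance* $2D\Delta t$ — the standard
Ermak–McCammon convention — giving a step RMS of
$\sqrt{2D\Delta t} \approx 0.045$ nm at the defaults. The integrator is
validated against free diffusion (MSD $= 2Dt$), the Boltzmann
distribution on double wells (against a quadrature oracle), and the
stationary variance $k_BT/\kappa$ of a harmonic well.

`buildLandscape()` draws a smooth double-well curve through anchor
wells: a C1 smoothstep base between anchors, clamped flat outside them,
plus a $\sin^2$ barrier bump between the two deepest anchors. The bump
vanishes with zero slope at the anchors, so anchor energies are
reproduced exactly (well depths of −22.81 and −10.05 kcal/mol at the
4 and 10 nm residence sites, the 100 mV conditions, give
$\Delta\Delta G = -12.76$ kcal/mol exactly; 1 kcal/mol = 1.688 kT at
25 °C). The barrier amplitude is a free parameter (default 3 kT): the
100 mV well-depth difference of ~21.5 kT would put essentially zero
occupancy in the shallow well, contradicting the observed level
occupancies, so cohort generation is calibrated to occupancies rather
than to that landscape (see below). The landscape remains an explicit
input for physics studies.

## Why long traces use a Markov switching engine

Direct integration at $\Delta t = 10^{-4}\ \mu s$ costs $10^{10}$ steps
per second of trace — far beyond what a validation suite should spend.
Long annotated traces therefore come from a two-tier design: the
Brownian simulator validates the physics at short timescales, and
cohort-scale traces use a continuous-time Markov chain (CTMC) over the
discrete levels, which is the level-resolved coarse-graining of the
same dynamics.

The CTMC is the "jump-to-stationary" chain $Q = \lambda(\Pi - I)$,
where each row of $\Pi$ is the occupancy vector $\pi$. Its stationary
distribution is exactly $\pi$ for any $\lambda > 0$, and — the property
everything else leans on — its autocovariance is a *single* exponential
with rate $\lambda$, so the level-switching current is a telegraph
process with the one-sided Lorentzian PSD

$$S(f) = \frac{4 v \lambda}{\lambda^2 + (2\pi f)^2},\qquad
  v = \sum_i \pi_i I_i^2 - \Big(\sum_i \pi_i I_i\Big)^2 .$$

## Calibration of the switching rate to I_N

I_N as measured is not a brickwall band integral: the event is
refiltered with an analog-prototype 8-pole Bessel low-pass at
$f_c = 100$ Hz and the periodogram is integrated over all retained
bins. `calibrateSwitchingRate()` therefore solves

$$\int_0^\infty S(f;\lambda)\,\lvert H_{\mathrm{Bessel}}(f;f_c)\rvert^2
  \,df \;=\; I_N^{\mathrm{target}\,2}$$

for $\lambda$ (by substitution $u = \arctan(2\pi f/\lambda)$ the
integrand is bounded and smooth, so plain quadrature plus `uniroot`
suffices). Matching the measurement definition matters: a brickwall
calibration over $[0, f_c]$ under-delivers the measured I_N by ~13 %
through the real chain (in-band Bessel droop, first-bin exclusion).

The analyte presets encode the study conditions: occupancies
4.98/91.25/3.77 % (free), 42.13/57.71/0.16 % (peptide complex),
13.29/86.66/0.05 % (small-molecule complex); dominant-level residual
currents 34.8 % (free and peptide complex, i.e. a 65.2 % blockade),
37.0 % and 48.9 % for the two small-molecule complexes; level spacing
38 percentage points between the two main residence sites, 25 % for the
rarely visited deepest level (a package default — no measured value
exists for it); I_N targets 16.3, 78.9, 28.2 and 36.3 pA at 100 Hz.
The resulting rates are $\lambda \approx 2790\ \mathrm{s^{-1}}$ (free),
258 (peptide complex), 2073 and 1142 $\mathrm{s^{-1}}$ — binding slows
the oscillation, which is exactly the physical story behind the I_N
contrast. Dwell and capture times are generator choices at the scale of
the recordings: mean event dwell 0.3 s (free) to 1.0 s (peptide
complex), capture every 0.15–0.2 s.

Additive noise is white (default RMS 2 % of the 500 pA open-pore
current at acquisition bandwidth) plus an optional $1/f^\alpha$ flicker
field synthesized spectrally; the telegraph dynamics, not the additive
noise, carry the I_N contrast between analytes.

## What the generator does *not* emulate

Real recordings contain baseline drift and wander, pore gating,
transient clogs, 50/60 Hz pickup, capacitance transients, and analyte
heterogeneity (partial unfolding, multiple simultaneous captures). The
generator produces none of these, and the detection thresholds are
tuned on clean baselines. Passing tests therefore demonstrate that the
analysis chain is *correct and unbiased under the stated model*, not
that it is robust to every artefact of a wet recording; on real data the
baseline estimator and the event screen are the stages most likely to
need adjustment.

# Acquisition and filtering

Defaults mimic the experiment: 100 kHz sampling with a 10 kHz 8-pole
low-pass Bessel "hardware" filter, then analysis refilters at 1 kHz or
100 Hz as each stage requires. Filters are applied causally
(forward-only), like the amplifier they mimic; the Bessel's nearly
constant group delay shifts both edges of a level dwell by the same
amount, which is why dwell durations and occupancies survive filtering
unbiased. The digital design is the analog prototype (reverse Bessel
polynomial roots, −3 dB normalized) through a prewarped bilinear
transform, applied as second-order sections — at cutoff/sampling ratios
of $10^{-3}$ a direct-form high-order IIR is numerically unusable, the
SOS cascade is exact. Validation cohorts sample at 25–50 kHz with
5–10 kHz hardware cutoffs, chosen so each analyte's switching is
resolved while keeping a 300-event cohort around $10^7$ samples; the
acquisition grid is an argument everywhere.

# Analysis choices

**Open-pore current.** The baseline is the highest-current peak of the
amplitude density, refined by a re-centred ±3 robust-SD trimmed mean
(the centre of a Gaussian fit to the histogram peak). A trace whose top
amplitude population holds <10 % of samples has no resolvable baseline
and is an error, not a guess.

**Event detection.** Hysteresis thresholding: intervals below
0.95·I₀ that dip below 0.85·I₀ at least once. Commercial event-analysis software does not document its event
criteria; hysteresis is the standard robust scheme — the 0.85 trigger sits safely
below baseline noise while the 0.95 delimiter catches the full event
extent, and the pair prevents chatter on shallow L1 levels. All
intervals are 0-based, half-open sample indices everywhere, including
serialized outputs.

**Per-event blockade.** The single ΔI/I₀ of a multi-level event is
computed from the event's *median* current: it is dominated by the
dominant level and insensitive to brief spikes. (Mean, median and dominant-level conventions all exist in the field;
the median is the choice made here, and on the synthetic
cohorts it reproduces the configured dominant-level blockade to
<0.1 %.)

**Level segmentation.** Amplitude-histogram idealization: kernel-density
peaks (bandwidth bounded by a first-difference noise estimate so that
discrete noise-free levels are not smeared into one kernel), shallow
valleys merged by a prominence rule, at most `max_levels` peaks kept,
samples cut at density valleys, and runs shorter than `min_level_dwell`
(default 5 samples) merged into their neighbours. A BIC-driven Gaussian
mixture was evaluated for this role and rejected: with a 5 %-occupancy
level the extra component is routinely absorbed into a broad catch-all
and the occupancy estimate collapses; the density-peak idealization
recovers the configured occupancies within sampling error (L2 within
~2 SE at 300 events). Labels are assigned by residual-current *rank*
(L1 shallowest), so they are stable under cohort subsampling; open
probabilities are time-weighted (total level dwell / total trapped
time), the natural reading of a stationary occupancy.

**I_N.** Plain (unwindowed) one-sided periodogram of the mean-removed
event segment, bin width = rate/N, satisfying Parseval exactly with the
denominator-N variance; I_N is the square root of the integral over
retained bins. The first non-DC bin is excluded (edge-discontinuity
leakage lands there); the exclusion count is a parameter, so the
alternative reading (drop only DC) is one flag away. Refiltering for
I_N trims a settle margin of $1/f_c$ from each end of the causal
filter's output; events shorter than 64 samples after trimming are
dropped with a message. Cohort I_N summaries additionally restrict to
events ≥0.5 s, because the first-bin exclusion removes a
duration-dependent slice of low-frequency power from short events and
would bias a cohort mean downward.

**Fingerprints and populations.** Each event becomes a point
(ΔI/I₀, I_N at 100 Hz); population structure is modelled as a
full-covariance 2D Gaussian mixture (via mclust), with
maximum-posterior assignment and ties to the lowest component index —
a reproducible stand-in for assigning events to density contours by
eye. Normalization for mixture-screening plots divides by the reference
cohort's Gaussian-peak blockade and mean I_N.

**Binding.** $F_c = 100\,N_{comp}/N_{total}$; the one-site law is fit
by unweighted nonlinear least squares (binomial-variance weighting is
available but off by default, matching the plain one-site fit
convention), with 95 % CIs from the fit covariance. The generator draws
complexed counts binomially with success probability
$\min(1, B_{max}X/(K_D+X))$: with the fitted saturation levels slightly
above 1 (B_max ≈ 1.1) the cap necessarily engages at high
concentration, which biases a refit K_D low by ~1.5 nM at the 19 nM
setting — visible, reported, and inside the ±4 nM comparison band.
Titrations that never leave saturation (or never reach it) are refused
as unidentifiable rather than fit.

**Competition.** Displacement of a pre-formed complex by a competing
ligand is modelled as first-order exchange, fraction displaced
$1 - e^{-kt}$, sampled per observation window; `populationTimecourse()`
recovers the windowed fractions from classified fingerprints.

# Numerical conventions and degenerate inputs

* Temperature is fixed at 298.15 K wherever units convert
  (RT/F = 25.693 mV; 1 kcal/mol = 1.688 kT).
* Constant traces/segments: density peaks fall back to a single atom;
  periodograms of constants are identically zero; I_N = 0.
* `ghkSelectivity()` raises a singularity error at the K⁺ Nernst
  potential (zero denominator), and the cylinder limit of the funnel
  conductance is exact when both diameters coincide.
* All stochastic entry points take a `seed`; given (seed, parameters)
  every output — including the full pipeline bundle — is
  bit-reproducible. R's RNG drives the C++ Brownian kernel too.
* Which two funnel diameters enter the conductance formula is an
  explicit argument (default *cis* entry × constriction); inverting a
  measured conductance for a pore size depends on that pairing, so it
  should never be implicit.

# Problem sizes used by the test suite

The suite and the acceptance script regenerate everything they measure:
two 300-event cohorts (free protein at 50 kHz, peptide complex at
25 kHz, ~$10^7$ samples each), Brownian ensembles of a few hundred
walkers at $10^5$–$3\times10^5$ steps, and titrations of 300 events per
concentration — sizes at which every comparison has its sampling error
controlled (3 SE bands) while a full run stays in the minutes range on
one core.

# Known limitations

* The CTMC telegraph has a single switching timescale per analyte; real
  level kinetics may be multi-exponential. The framework accepts a full
  rate matrix (`checkStationary()` validates it against the occupancies)
  but the presets do not use one.
* The position→current map is piecewise-linear and static; it ignores
  voltage dependence within a cohort (voltage trends are analyzed across
  cohorts instead).
* The dipole-moment mechanism linking binding to noise is represented
  only through its observable (the I_N target), not as a forward
  physical model.
* Binding analysis is equilibrium-only: no $k_{on}/k_{off}$ estimation
  from voltage-dependent trapping, and no surface-kinetics model.
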