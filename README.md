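# nanofp

Single-molecule analysis of protein–drug interactions (PDIs) with large
funnel-shaped biological nanopores, plus a calibrated synthetic-trace
generator for validating the whole chain.

## The problem and who this is for

A funnel-shaped pore (e.g. the YaxAB toxin pore: ~18 nm long, 10 nm *cis*
entry, 1.9 nm constriction) traps a single folded protein
electro-osmotically. The trapped protein oscillates between residence
sites along the pore axis, so one capture–trap–escape event shows several
discrete current levels (L1–L3). Two per-event statistics fingerprint the
analyte:

- the **current blockade** ΔI/I₀ = 100·(I₀ − I)/I₀ (%), taken from the
  event's median current, and
- the **current noise** I_N = √(Σᵢ Pᵢ Δf) (pA), the square root of the
  one-sided event periodogram integrated over retained bins after a
  100 Hz 8-pole Bessel refilter, with the first non-DC bin excluded.

Ligand binding barely changes the blockade but slows the level-switching
dynamics, which concentrates fluctuation power below 100 Hz and raises
I_N several-fold — that is the discrimination axis. Counting
ligand-bound events across a titration gives the bound fraction
F_c = 100·N_comp/N_total, fit by the one-site law
**Y = B_max·X/(K_D + X)** for the dissociation constant. The package is
aimed at nanopore electrophysiologists and method developers who need a
reproducible, scriptable version of this pipeline.

The generator side models the physics: overdamped Brownian dynamics
z(t+Δt) = z(t) + (D/k_BT)·F(z)·Δt + S on a double-well free-energy
landscape ΔG(z) (S centred normal, variance 2DΔt), a monotone map from
axial position to residual current, and — for long annotated traces — a
continuous-time Markov level-switching engine whose jump rate is
calibrated in closed form so the sub-100 Hz RMS of the switching
telegraph matches a target I_N. Pore biophysics utilities cover the
funnel-conductance formula G = σ_s·π·d_in·d_out/(4L), the
Goldman–Hodgkin–Katz permeability ratio from reversal potentials, and
ion-flux→current conversion (1 ns⁻¹ ↔ 160.218 pA for |z| = 1).

## Worked example

```r
library(nanofp)

# annotated synthetic recording of the free protein: 500 pA open pore,
# 50 kHz sampling, 10 kHz 8-pole hardware Bessel, 2% white noise
sim <- generateEventTrain(freeProteinProfile(), NoiseModel(10), Io = 500,
                          sampling_rate = 50000, duration = 1, seed = 11,
                          min_event_s = 0.05, hardware_cutoff = 10000,
                          n_events = 300)

io <- estimateOpenCurrent(sim$trace)
ev <- detectEvents(sim$trace, io, min_duration = 0.02)
segs <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
  segmentLevels(ev[i, ], sim$trace)))
openProbabilities(segs)
#>   level open_prob_pct mean_ires_pct mean_duration_s total_time_s
#> 1    L1      5.876620      64.71115    0.0005929327       6.5021
#> 2    L2     90.543235      34.91467    0.0052910236     100.1802
#> 3    L3      3.580146      25.22232    0.0004630275       3.9612

blockadeStatistics(ev)$blockade_pct
#> [1] 65.17495
```

The cohort was generated at occupancies 4.98 / 91.25 / 3.77 % and a
65.2 % dominant-level blockade; the blind segmentation recovers
5.9 / 90.5 / 3.6 % and 65.17 %. I_N separates free protein from a
peptide-bound complex (targets 16.3 vs 78.9 pA at 100 Hz):

```r
fp <- fingerprintEvents(ev, sim$trace, cutoff = 100)
mean(fp$in_pA)
#> [1] 15.23437
```

and a titration fit recovers the binding constant:

```r
ts <- generateTitration(KD = 19, Bmax = 1.11,
                        concentrations = c(1, 2, 5, 10, 20, 50, 100, 200, 500),
                        events_per_point = 300, seed = 29)
fitBinding(ts)$KD_nM
#> [1] 18.8386
```

A command-line front end over the same functions lives at
`inst/cli/nanofp.R`
(`Rscript inst/cli/nanofp.R simulate|detect|levels|noise|fingerprint|titrate|compete|pore|run`),
and `runPipeline(defaultPipelineConfig(seed))` chains every stage with
full determinism under a fixed seed.

See `vignettes/nanofp-methods.Rmd` for the model, its assumptions, the
calibration maths and the package's design choices.

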