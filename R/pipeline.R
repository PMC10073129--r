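## Seeded end-to-end demo pipeline: simulate -> detect -> levels -> noise ->
## fingerprint -> titrate -> compete, writing a versioned result bundle.

#' Default pipeline configuration
#'
#' A compact, fully specified configuration for [runPipeline()]: two
#' analyte profiles (free protein and the Bak-BH3 complex), modest
#' cohort sizes, 25 kHz acquisition with a 5 kHz hardware filter, the
#' standard detection thresholds, a titration at the tightest-binder
#' K_D and a competition time-course.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory for the result bundle.
#' @return A nested list; serializable losslessly to/from JSON.
#' @export
defaultPipelineConfig <- function(seed = 1, outdir = tempfile("nanofp_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    acquisition = list(sampling_rate_hz = 25000, hardware_cutoff_hz = 5000,
                       Io_pA = 500),
    analysis = list(entry_threshold = 0.85, exit_threshold = 0.95,
                    min_duration_s = 0.005, in_cutoff_hz = 100,
                    max_levels = 3),
    simulate = list(profiles = c("free", "bak-bh3"), duration_s = 8,
                    min_event_s = 0.05, white_rms_pA = 10),
    titration = list(KD_nM = 19, Bmax = 1.11,
                     concentrations_nM = c(1, 2, 5, 10, 20, 50, 100, 200,
                                           500),
                     events_per_point = 300),
    competition = list(k_per_s = 0.0008,
                       window_times_s = c(0, 600, 1200, 2400),
                       events_per_window = 200)
  )
}

.profileByName <- function(name, Io) {
  switch(name,
    "free" = freeProteinProfile(Io),
    "bak-bh3" = bakBH3ComplexProfile(Io),
    "abt-737" = abt737ComplexProfile(Io),
    "a-1331852" = a1331852ComplexProfile(Io),
    stop("unknown profile: ", name))
}

# md5 of the canonical JSON serialization of the config
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the seeded end-to-end pipeline
#'
#' Chains every stage of the package on synthetic data: per profile,
#' generate an annotated event train, detect events, segment levels and
#' collect open probabilities, compute I_N fingerprints; then fit the
#' 2D population model across profiles, generate and fit a titration,
#' and generate a competition time-course. All randomness derives from
#' `config$seed`: the same configuration produces identical outputs.
#'
#' @param config configuration list, see [defaultPipelineConfig()]; or a
#'   path to a JSON file of one.
#' @return A result bundle: list with `config_hash`, `files` (named
#'   vector of written file paths), and in-memory `summaries` per stage.
#'   Every referenced file exists on return.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(); summaries <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  acq <- config$acquisition; ana <- config$analysis
  fps <- list()
  for (pi in seq_along(config$simulate$profiles)) {
    pname <- config$simulate$profiles[pi]
    prof <- stage(paste0("simulate:", pname),
                  .profileByName(pname, acq$Io_pA))
    sim <- stage(paste0("simulate:", pname),
      generateEventTrain(prof, NoiseModel(config$simulate$white_rms_pA),
                         Io = acq$Io_pA,
                         sampling_rate = acq$sampling_rate_hz,
                         duration = config$simulate$duration_s,
                         seed = config$seed + 101 * pi,
                         min_event_s = config$simulate$min_event_s,
                         hardware_cutoff = acq$hardware_cutoff_hz))
    tr_path <- file.path(config$outdir, paste0("trace_", pname, ".csv"))
    an_path <- file.path(config$outdir, paste0("annotation_", pname,
                                               ".json"))
    writeTrace(sim$trace, tr_path)
    writeAnnotation(sim$annotation, an_path)
    files[paste0("trace_", pname)] <- tr_path
    files[paste0("annotation_", pname)] <- an_path

    io <- stage(paste0("baseline:", pname), estimateOpenCurrent(sim$trace))
    ev <- stage(paste0("detect:", pname),
      detectEvents(sim$trace, io, ana$entry_threshold, ana$exit_threshold,
                   ana$min_duration_s))
    ev_path <- file.path(config$outdir, paste0("events_", pname, ".csv"))
    utils::write.csv(ev, ev_path, row.names = FALSE)
    files[paste0("events_", pname)] <- ev_path

    segs <- stage(paste0("levels:", pname),
      do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
        segmentLevels(ev[i, ], sim$trace, max_levels = ana$max_levels))))
    op <- openProbabilities(segs)
    op_path <- file.path(config$outdir, paste0("levels_", pname, ".csv"))
    utils::write.csv(op, op_path, row.names = FALSE)
    files[paste0("levels_", pname)] <- op_path

    fp <- stage(paste0("fingerprint:", pname),
      fingerprintEvents(ev, sim$trace, cutoff = ana$in_cutoff_hz,
                        label = pname))
    fps[[pname]] <- fp
    summaries[[paste0("cohort_", pname)]] <- list(
      Io_pA = io, n_events = nrow(ev),
      blockade = if (nrow(ev) >= 20) blockadeStatistics(ev) else NULL,
      open_probabilities = op,
      mean_in_pA = mean(fp$in_pA))
  }
  allfp <- do.call(rbind, fps)
  fp_path <- file.path(config$outdir, "fingerprints.csv")
  utils::write.csv(allfp, fp_path, row.names = FALSE)
  files["fingerprints"] <- fp_path

  if (length(fps) >= 2 && nrow(allfp) >= 20 * length(fps)) {
    model <- stage("populations",
      fitPopulations(allfp, K = length(fps), seed = config$seed))
    cls <- classifyEvents(allfp, model)
    acc <- stage("populations", {
      tab <- table(cls$label, cls$population)
      sum(apply(tab, 2, max)) / sum(tab)
    })
    summaries$populations <- list(means = model$means,
                                  weights = model$weights,
                                  purity = acc)
  }

  tit <- stage("titrate",
    generateTitration(config$titration$KD_nM, config$titration$Bmax,
                      config$titration$concentrations_nM,
                      config$titration$events_per_point,
                      seed = config$seed + 7))
  fitb <- stage("titrate", fitBinding(tit))
  tit_path <- file.path(config$outdir, "titration.csv")
  utils::write.csv(titrationTable(tit), tit_path, row.names = FALSE)
  files["titration"] <- tit_path
  summaries$binding <- list(KD_nM = fitb$KD_nM, KD_ci = fitb$KD_ci,
                            Bmax = fitb$Bmax)

  cmp <- stage("compete",
    generateCompetitionTimecourse("bak-bh3", "abt-737",
                                  config$competition$k_per_s,
                                  config$competition$window_times_s,
                                  config$competition$events_per_window,
                                  seed = config$seed + 13))
  cmp_path <- file.path(config$outdir, "competition.csv")
  utils::write.csv(cmp, cmp_path, row.names = FALSE)
  files["competition"] <- cmp_path
  summaries$competition <- cmp

  stopifnot(all(file.exists(files)))
  list(config_hash = .configHash(config), files = files,
       summaries = summaries)
}
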