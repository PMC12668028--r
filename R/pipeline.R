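## End-to-end orchestration: simulate -> bin -> classify -> fit ->
## thermodynamics -> finite-size scaling, with a content-addressed manifest
## and resumable stages, plus ingestion of recording-style event lists.

#' Construct an experiment plan
#'
#' @param state dynamical regime: "sub", "crit" or "super".
#' @param nValues system sizes to simulate.
#' @param replicates independent network configurations per size (the
#'   production design uses 5).
#' @param binWidth bin duration in timesteps (5 for model data).
#' @param nBins recording length in bins.
#' @param schedule a \linkS4class{LearningSchedule}.
#' @param sampler a \linkS4class{SamplerConfig} for model evaluation.
#' @param masterSeed integer; every stage seed derives from it.
#' @param outputDir artifact directory.
#' @return an \linkS4class{ExperimentPlan}.
#' @export
experimentPlan <- function(state = "crit", nValues = c(20L, 40L, 80L, 100L),
                           replicates = 5L, binWidth = 5, nBins = 1e7,
                           schedule = learningSchedule(),
                           sampler = samplerConfig(nSamples = 3e4,
                                                   nChains = 100L),
                           masterSeed = 1L, outputDir = "spikeMaxEnt-run") {
  new("ExperimentPlan", state = state, nValues = as.integer(nValues),
      replicates = as.integer(replicates), binWidth = binWidth,
      nBins = nBins, schedule = schedule, sampler = sampler,
      masterSeed = as.integer(masterSeed), outputDir = outputDir)
}

#' Run an experiment plan end to end
#'
#' For every (N, replicate): calibrate \eqn{\delta u_{rec}} (once per N,
#' shared across replicates), build and pre-train a network, record
#' spikes, bin, compute moments, classify the avalanche state, fit the
#' K-pairwise model, sweep its thermodynamics, and finally fit the
#' finite-size scaling of the Cv and chi maxima across N.  Every artifact
#' is written under \code{plan@outputDir} and entered into a manifest with
#' its MD5 digest; stages whose outputs already exist with matching
#' digests are skipped, making interrupted runs resumable.  The whole run
#' is deterministic given \code{plan@masterSeed}.
#'
#' @param plan an \linkS4class{ExperimentPlan}.
#' @param calibration optional named list mapping as.character(N) to
#'   pre-computed critical deltaURec values (skips calibration).
#' @param thermoGrid temperature grid for the sweeps.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest data.frame (artifact, path, md5).
#' @export
runPlan <- function(plan, calibration = NULL,
                    thermoGrid = defaultTemperatureGrid(), quiet = FALSE) {
  dir.create(plan@outputDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(plan@outputDir, "manifest.tsv")
  manifest <- if (file.exists(manifestPath))
    read.table(manifestPath, sep = "\t", header = TRUE,
               stringsAsFactors = FALSE)
  else data.frame(artifact = character(0), path = character(0),
                  md5 = character(0), stringsAsFactors = FALSE)
  say <- function(...) if (!quiet) message("[runPlan] ", ...)
  fresh <- function(path) {
    row <- manifest[manifest$path == path, , drop = FALSE]
    nrow(row) == 1 && file.exists(path) &&
      unname(tools::md5sum(path)) == row$md5
  }
  record <- function(artifact, path) {
    manifest <<- manifest[manifest$path != path, , drop = FALSE]
    manifest <<- rbind(manifest,
                       data.frame(artifact = artifact, path = path,
                                  md5 = unname(tools::md5sum(path)),
                                  stringsAsFactors = FALSE))
    write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  stageError <- function(stage, n, rep, e)
    stop("stage '", stage, "' failed for N=", n, " replicate ", rep, ": ",
         conditionMessage(e), call. = FALSE)

  maxima <- data.frame()
  for (n in plan@nValues) {
    dUcrit <- if (!is.null(calibration) &&
                  !is.null(calibration[[as.character(n)]]))
      calibration[[as.character(n)]]
    else {
      say("calibrating deltaURec for N = ", n)
      calibrateDeltaURec(n, dynamicsParams(),
                         seed = deriveSeed(plan@masterSeed, "calib", n))$estimate
    }
    dU <- deltaURecForState(dUcrit, plan@state)
    params <- dynamicsParams(deltaURec = dU)
    for (rep in seq_len(plan@replicates)) {
      tag <- sprintf("N%03d_r%02d", n, rep)
      evPath <- file.path(plan@outputDir, paste0("events_", tag, ".tsv"))
      moPath <- file.path(plan@outputDir, paste0("moments_", tag, ".tsv"))
      mdPath <- file.path(plan@outputDir, paste0("model_", tag, ".txt"))
      thPath <- file.path(plan@outputDir, paste0("thermo_", tag, ".tsv"))
      clPath <- file.path(plan@outputDir, paste0("classify_", tag, ".txt"))

      if (!fresh(evPath)) {
        say("simulating ", tag)
        tryCatch({
          topo <- buildNetwork(n, params,
                               seed = deriveSeed(plan@masterSeed, "topo", n, rep))
          topo <- pretrainNetwork(topo, params,
                                  seed = deriveSeed(plan@masterSeed, "pre", n, rep))
          run <- runRecording(topo, params,
                              nTimesteps = plan@nBins * plan@binWidth,
                              seed = deriveSeed(plan@masterSeed, "rec", n, rep))
          writeSpikeEvents(run$events, evPath)
          cls <- classifyState(avalancheDistributions(run$catalog), n)
          writeLines(c(paste0("label=", cls$label),
                       paste(names(cls$evidence),
                             format(cls$evidence, digits = 8), sep = "=")),
                     clPath)
          record("events", evPath); record("classification", clPath)
        }, error = function(e) stageError("simulate", n, rep, e))
      }
      if (!fresh(moPath)) {
        say("moments ", tag)
        tryCatch({
          raster <- binEvents(readSpikeEvents(evPath), plan@binWidth)
          writeMoments(computeMoments(raster), moPath)
          record("moments", moPath)
        }, error = function(e) stageError("moments", n, rep, e))
      }
      if (!fresh(mdPath)) {
        say("fitting ", tag)
        tryCatch({
          fit <- fitKPairwise(readMoments(moPath), plan@schedule,
                              seed = deriveSeed(plan@masterSeed, "fit", n, rep))
          writeKPairwiseModel(fit$model, mdPath)
          record("model", mdPath)
        }, error = function(e) stageError("fit", n, rep, e))
      }
      if (!fresh(thPath)) {
        say("thermodynamics ", tag)
        tryCatch({
          model <- readKPairwiseModel(mdPath)
          cfg <- plan@sampler
          cfg@seed <- deriveSeed(plan@masterSeed, "thermo", n, rep)
          curve <- responseCurve(model, thermoGrid, cfg)
          writeThermoCurve(curve, thPath)
          record("thermo", thPath)
        }, error = function(e) stageError("thermo", n, rep, e))
      }
      curve <- readThermoCurveFile(thPath)
      for (obs in c("cv", "chi")) {
        mx <- locateMaximum(curve, obs)
        maxima <- rbind(maxima,
                        data.frame(n = n, replicate = rep, observable = obs,
                                   value = mx$value, tmax = mx$tMax))
      }
    }
  }
  if (length(unique(maxima$n)) >= 2) {
    scPath <- file.path(plan@outputDir, "scaling.tsv")
    rows <- lapply(c("cv", "chi"), function(obs) {
      d <- maxima[maxima$observable == obs, ]
      sf <- finiteSizeScaling(d[, c("n", "value", "replicate", "tmax")],
                              seed = deriveSeed(plan@masterSeed, "boot", obs))
      data.frame(observable = obs, exponent = sf@exponent,
                 exponentSe = sf@exponentSe)
    })
    write.table(do.call(rbind, rows), scPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    record("scaling", scPath)
  }
  invisible(manifest)
}

readThermoCurveFile <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  new("ThermoCurve", temperatures = df$T, cv = df$cv, cvSe = df$cv_se,
      chi = df$chi, chiSe = df$chi_se, initMode = as.character(df$init_mode[1]))
}

#' Ingest a recording-style event list
#'
#' Reads a spike event file whose clock unit is milliseconds (the
#' \code{dt_ms} header), bins it at \code{binMs} (25 ms by default, giving
#' about \eqn{1.4 \times 10^5} bins for an hour-long 60-channel
#' recording), and computes the constrained statistics -- the same
#' downstream path simulated data takes.
#'
#' @param path event-list file (see \code{\link{writeSpikeEvents}}).
#' @param dtMs clock unit in ms, overriding the file header if given.
#' @param binMs bin duration in milliseconds.
#' @return list with \code{raster} (\linkS4class{BinnedRaster}) and
#'   \code{moments} (\linkS4class{MomentSet}).
#' @export
ingestRecording <- function(path, dtMs = NULL, binMs = 25) {
  events <- readSpikeEvents(path)
  if (!is.null(dtMs)) events@dtMs <- dtMs
  if (is.na(events@dtMs))
    stop("recording ingestion needs a millisecond clock (dt_ms header)")
  binWidth <- binMs / events@dtMs
  raster <- binEvents(events, binWidth)
  list(raster = raster, moments = computeMoments(raster))
}
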