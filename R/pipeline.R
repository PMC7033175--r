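## End-to-end pipeline drivers: simulate presets, process traces, build
## gates from calibration samples and classify the mixture. Each stage
## records its outputs (with checksums and seeds) in a run manifest.

.manifestPath <- function(dir) file.path(dir, "manifest.json")

.updateManifest <- function(dir, stage, entry) {
  path <- .manifestPath(dir)
  manifest <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else list()
  entry$files <- lapply(entry$files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  manifest[[stage]] <- entry
  manifest$package_version <-
    as.character(utils::packageVersion("impedCyto"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a preset sample to disk
#'
#' Writes `<preset>_trace.csv` (wide trace CSV) and `<preset>_truth.csv`
#' (ground-truth event log) into `outDir` and records them, with the
#' seed, in `manifest.json`. Output is byte-identical for identical
#' (preset, seed, overrides).
#'
#' @param preset preset name (see [presetPopulations()]).
#' @param seed integer RNG seed.
#' @param outDir output directory (created if needed).
#' @param ... overrides forwarded to [presetSample()].
#' @return Named list of written file paths, invisibly.
#' @export
cmdSimulate <- function(preset, seed, outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- presetSample(preset, seed = seed, ...)
  tracePath <- file.path(outDir, paste0(preset, "_trace.csv"))
  truthPath <- file.path(outDir, paste0(preset, "_truth.csv"))
  writeTrace(sim$trace, tracePath)
  writeEvents(sim$events, truthPath)
  .updateManifest(outDir, paste0("simulate_", preset),
    list(seed = seed, n_events = nrow(sim$events),
         files = list(tracePath, truthPath)))
  invisible(list(trace = tracePath, truth = truthPath))
}

#' Process a trace file into a detected-event table
#'
#' Runs the wavelet detrend/denoise chain and peak detection on every
#' channel of a stored trace and writes the events CSV; filter and
#' detection settings are logged in the run manifest.
#'
#' @param traceFile path to a trace CSV (schema of [writeTrace()]).
#' @param outFile output events CSV path; defaults to the trace path
#'   with `_trace` replaced by `_events`.
#' @param cfg a [filterConfig()].
#' @param referenceFrequencyHz detection channel; an error names the
#'   available channels if it is absent from the trace.
#' @param k detection threshold in sigma units.
#' @param pulseWidthS nominal pulse width, seconds.
#' @return Path of the events CSV, invisibly; the detected events are
#'   attached as attribute `"events"`.
#' @export
cmdProcess <- function(traceFile, outFile = NULL, cfg = filterConfig(),
                       referenceFrequencyHz = 5e5, k = 5,
                       pulseWidthS = 1e-3) {
  trace <- readTrace(traceFile)
  if (is.null(outFile))
    outFile <- sub("(_trace)?\\.csv$", "_events.csv", traceFile)
  res <- processTrace(trace, cfg, referenceFrequencyHz, k, pulseWidthS)
  writeEvents(res$events, outFile)
  .updateManifest(dirname(outFile),
    paste0("process_", sub("\\.csv$", "", basename(traceFile))),
    list(trace = traceFile, n_events = nrow(res$events),
         filter = cfg[c("wavelet", "thresholdRule", "thresholdMode")],
         k_sigma = k, reference_frequency_hz = referenceFrequencyHz,
         noise_sigma_uv = as.list(res$noiseSigma),
         files = list(outFile)))
  structure(invisible(outFile), events = res$events)
}

#' Analyze calibration and mixture event tables
#'
#' Reproduces the full classification workflow: builds bead and cell
#' gates from the two calibration samples, derives the aggregate gate
#' from mixture events falling outside the bead gate, classifies the
#' mixture by ellipse gating and by the 10 uV amplitude threshold, fits
#' amplitude mixtures (with a 1-vs-2 component BIC comparison), and runs
#' the Welch bead-vs-cell separability test. Writes labelled events,
#' counts, gate/fit parameter JSONs and a report JSON to `outDir`.
#'
#' @param beadEvents,cellEvents,mixtureEvents detected-event tables
#'   (data.frames) or paths to events CSVs.
#' @param outDir output directory.
#' @param fLow,fHigh gating frequencies, Hz.
#' @param scale ellipse boundary in standard deviations.
#' @param exclusionScale bead-gate Mahalanobis radius used when selecting
#'   the mixture events that estimate the aggregate gate. A 1-SD ellipse
#'   contains only ~39 percent of its own population, so excluding merely
#'   `scale` would leave most beads in the aggregate-gate estimate;
#'   3 SD covers ~99 percent of beads.
#' @param thresholdUv amplitude threshold for the 1-D rule, uV.
#' @param referenceFrequencyHz reference channel, Hz.
#' @param figures also write the amplitude-histogram and SNR-scatter
#'   images (PNG) via [plotAmplitudeDistributions()] / [plotSnrScatter()].
#' @return The report as a list (also written to `report.json`).
#' @export
cmdAnalyze <- function(beadEvents, cellEvents, mixtureEvents, outDir,
                       fLow = 5e5, fHigh = 2e7, scale = 1,
                       exclusionScale = 3, thresholdUv = 10,
                       referenceFrequencyHz = 5e5, figures = FALSE) {
  asEvents <- function(x) if (is.character(x)) readEvents(x) else x
  bead <- asEvents(beadEvents)
  cell <- asEvents(cellEvents)
  mixture <- asEvents(mixtureEvents)
  if (nrow(bead) == 0 || nrow(cell) == 0 || nrow(mixture) == 0)
    stop("empty event table(s): all three samples must contain events",
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  beadGate <- buildGate(bead, fLow, fHigh, scale, name = "bead")
  cellGate <- buildGate(cell, fLow, fHigh, scale, name = "cell")
  outsideBead <- mixture[gateDistance(beadGate, mixture) > exclusionScale,
                         , drop = FALSE]
  if (nrow(outsideBead) < 3)
    stop("too few mixture events outside the bead gate to estimate the ",
         "aggregate covariance", call. = FALSE)
  aggGate <- buildGate(outsideBead, fLow, fHigh, scale,
                       name = "aggregate")

  cls <- classifyEvents(mixture, beadGate, aggGate, cellGate)
  thr <- thresholdClassify(mixture, thresholdUv, referenceFrequencyHz)

  beadAmps <- referenceAmplitudes(bead, referenceFrequencyHz)
  cellAmps <- referenceAmplitudes(cell, referenceFrequencyHz)
  mixAmps <- referenceAmplitudes(mixture, referenceFrequencyHz)
  beadSel <- selectMixtureComponents(beadAmps, 1:2,
                                     sampleName = "pure_beads")
  mixSel <- selectMixtureComponents(mixAmps, 1:2, sampleName = "mixture")
  cellFit <- fitAmplitudeMixture(cellAmps, 1, sampleName = "pure_cells")
  welch <- comparePopulations(beadAmps, cellAmps)

  labelledPath <- file.path(outDir, "mixture_labelled.csv")
  writeEvents(cls$events, labelledPath)
  countsPath <- file.path(outDir, "counts.csv")
  countsDf <- data.frame(
    method = c(rep("ellipse", length(cls$counts)),
               rep("threshold", length(thr$counts))),
    label = c(names(cls$counts), names(thr$counts)),
    count = c(as.integer(cls$counts), as.integer(thr$counts)))
  data.table::fwrite(countsDf, countsPath)
  gatesPath <- file.path(outDir, "gates.json")
  jsonlite::write_json(
    lapply(list(beadGate, cellGate, aggGate), gateToList),
    gatesPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  fitsPath <- file.path(outDir, "mixture_fits.json")
  jsonlite::write_json(
    list(pure_beads = mixtureToList(beadSel$fits[["2"]]),
         mixture = mixtureToList(mixSel$fits[["2"]]),
         pure_cells = mixtureToList(cellFit),
         bic = list(pure_beads = as.list(beadSel$bic),
                    mixture = as.list(mixSel$bic))),
    fitsPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)

  figFiles <- list()
  if (figures) {
    histPath <- file.path(outDir, "amplitude_distributions.png")
    scatterPath <- file.path(outDir, "snr_scatter.png")
    ggplot2::ggsave(histPath, plotAmplitudeDistributions(
      list(pure_beads = beadAmps, pure_cells = cellAmps,
           mixture = mixAmps), thresholdUv = thresholdUv),
      width = 7, height = 4, dpi = 120)
    ggplot2::ggsave(scatterPath, plotSnrScatter(
      list(bead = bead, cell = cell, mixture = mixture),
      gates = list(beadGate, cellGate, aggGate), fLow = fLow,
      fHigh = fHigh), width = 6, height = 5, dpi = 120)
    figFiles <- list(histPath, scatterPath)
  }

  report <- list(
    counts = list(ellipse = as.list(cls$counts),
                  threshold = as.list(thr$counts)),
    aggregate_count = unname(cls$counts[["aggregate"]]),
    aggregate_count_threshold = unname(thr$counts[["aggregate"]]),
    mixture_fits = list(
      pure_beads = mixtureToList(beadSel$fits[["2"]]),
      mixture = mixtureToList(mixSel$fits[["2"]]),
      pure_cells = mixtureToList(cellFit)),
    bic_best = list(pure_beads = beadSel$best, mixture = mixSel$best),
    bead_vs_cell = welch,
    n_events = list(bead = nrow(bead), cell = nrow(cell),
                    mixture = nrow(mixture)))
  reportPath <- file.path(outDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  .updateManifest(outDir, "analyze",
    list(gating = list(f_low_hz = fLow, f_high_hz = fHigh, scale = scale,
                       threshold_uv = thresholdUv),
         files = c(list(labelledPath, countsPath, gatesPath, fitsPath,
                        reportPath), figFiles)))
  report
}

#' Run the complete preset pipeline
#'
#' Simulate the three preset samples, process each trace, and analyze the
#' resulting event tables; the standard end-to-end reproduction used by
#' the worked examples.
#'
#' @param outDir working directory for all stage outputs.
#' @param seeds named (or length-3) integer seeds for the pure_beads,
#'   pure_cells and mixture simulations.
#' @param figures forwarded to [cmdAnalyze()].
#' @param ... forwarded to [cmdAnalyze()] (gating settings).
#' @return The analysis report (list), with the per-sample detected and
#'   injected event counts under `$n_events` / `$n_injected`.
#' @export
runPresetPipeline <- function(outDir, seeds = c(pure_beads = 101L,
                                                pure_cells = 202L,
                                                mixture = 303L),
                              figures = FALSE, ...) {
  presets <- c("pure_beads", "pure_cells", "mixture")
  if (is.null(names(seeds))) names(seeds) <- presets
  ev <- list(); injected <- list()
  for (p in presets) {
    files <- cmdSimulate(p, seed = seeds[[p]], outDir = outDir)
    out <- cmdProcess(files$trace)
    ev[[p]] <- attr(out, "events")
    injected[[p]] <- nrow(readEvents(files$truth))
  }
  report <- cmdAnalyze(ev$pure_beads, ev$pure_cells, ev$mixture,
                       outDir = outDir, figures = figures, ...)
  report$n_injected <- injected
  report$n_detected <- lapply(ev, nrow)
  report
}
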