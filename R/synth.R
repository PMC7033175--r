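## Seeded generator of multi-frequency lock-in traces with ground truth.
##
## A trace is drift + white noise + a train of Gaussian transit pulses.
## Event amplitudes are parameterised directly in uV at the 500 kHz
## reference channel (the measured-voltage-to-ohms conversion of the
## acquisition chain is not modelled); the circuit model supplies the
## relative cross-frequency scaling, so beads are flat across channels
## while cells and aggregates decline at high frequency.

#' Population specification for the trace generator
#'
#' @param kind `"bead"`, `"bead_doublet"`, `"cell"` or `"aggregate"`.
#' @param weight fraction of events drawn from this population (weights
#'   across a sample must sum to 1).
#' @param ampMeanUv mean peak amplitude at the reference frequency, uV.
#' @param ampCv coefficient of variation of the amplitude (in [0, 1)).
#' @param particle a [ParticleModel-class] used for cross-frequency
#'   scaling; defaults by kind (doublets scale like beads: flat).
#' @return A list of class `PopulationSpec`.
#' @seealso [presetPopulations()], [generateTrace()]
#' @export
populationSpec <- function(kind, weight, ampMeanUv, ampCv,
                           particle = NULL) {
  kinds <- c("bead", "bead_doublet", "cell", "aggregate")
  if (!kind %in% kinds)
    stop("'kind' must be one of ", paste(kinds, collapse = ", "),
         call. = FALSE)
  if (weight < 0 || weight > 1)
    stop("'weight' must be in [0, 1]", call. = FALSE)
  if (!is.finite(ampMeanUv) || ampMeanUv <= 0)
    stop("'ampMeanUv' must be positive", call. = FALSE)
  if (!is.finite(ampCv) || ampCv < 0 || ampCv >= 1)
    stop("'ampCv' must be in [0, 1)", call. = FALSE)
  if (is.null(particle))
    particle <- switch(kind,
      bead = beadParticle(),
      bead_doublet = beadParticle(deltaR = 200, radiusUm = 1.4 * 2^(1 / 3)),
      cell = cellParticle(),
      aggregate = aggregateParticle())
  structure(list(kind = kind, weight = weight, ampMeanUv = ampMeanUv,
                 ampCv = ampCv, particle = particle),
            class = "PopulationSpec")
}

#' Trace acquisition configuration
#'
#' Defaults emulate a 20 s acquisition at 40 kHz demodulated sampling on
#' the five-frequency grid, with 1 ms transit pulses, 0.3 uV white noise
#' per channel, and a slow sinusoidal baseline drift (5 uV amplitude,
#' 30 s period) plus an optional linear ramp.
#'
#' @param frequencies excitation frequency grid, Hz.
#' @param samplingRateHz demodulated samples per second.
#' @param durationS trace duration, seconds.
#' @param nEvents number of transit events to embed.
#' @param pulseWidthS nominal transit duration (the Gaussian pulse has
#'   sigma = pulseWidthS/4), seconds.
#' @param noiseSigmaUv additive white-noise standard deviation per
#'   channel, uV.
#' @param driftAmplitudeUv,driftPeriodS sinusoidal baseline drift.
#' @param rampUvPerS optional linear baseline ramp, uV per second.
#' @param referenceFrequencyHz channel in which `ampMeanUv` is specified.
#' @param seed integer RNG seed; every stochastic draw in the generator
#'   is governed by it.
#' @return A list of class `TraceConfig`.
#' @export
traceConfig <- function(frequencies = defaultFrequencyGrid(),
                        samplingRateHz = 4e4, durationS = 20,
                        nEvents = 300, pulseWidthS = 1e-3,
                        noiseSigmaUv = 0.3, driftAmplitudeUv = 5,
                        driftPeriodS = 30, rampUvPerS = 0,
                        referenceFrequencyHz = 5e5, seed = 1L) {
  .checkFrequencies(frequencies)
  if (nEvents < 0) stop("'nEvents' must be non-negative", call. = FALSE)
  if (pulseWidthS <= 0 || durationS <= 0 || samplingRateHz <= 0)
    stop("durations and rates must be positive", call. = FALSE)
  if (pulseWidthS * nEvents >= durationS)
    stop("events do not fit: pulseWidthS * nEvents must be < durationS",
         call. = FALSE)
  if (samplingRateHz <= 2 / pulseWidthS)
    stop("sampling rate too low to resolve pulses ",
         "(need samplingRateHz > 2/pulseWidthS)", call. = FALSE)
  if (noiseSigmaUv < 0 || driftAmplitudeUv < 0)
    stop("noise and drift amplitudes must be non-negative", call. = FALSE)
  .matchFrequency(referenceFrequencyHz, frequencies, "frequency grid")
  structure(list(frequencies = frequencies,
                 samplingRateHz = samplingRateHz, durationS = durationS,
                 nEvents = as.integer(nEvents), pulseWidthS = pulseWidthS,
                 noiseSigmaUv = noiseSigmaUv,
                 driftAmplitudeUv = driftAmplitudeUv,
                 driftPeriodS = driftPeriodS, rampUvPerS = rampUvPerS,
                 referenceFrequencyHz = referenceFrequencyHz,
                 seed = as.integer(seed)),
            class = "TraceConfig")
}

#' Draw reference-frequency amplitudes for a population
#'
#' Amplitudes are normal with mean `ampMeanUv` and sd
#' `ampCv * ampMeanUv`, truncated to be positive (non-positive draws are
#' rejected and redrawn).
#'
#' @param spec a [populationSpec()].
#' @param n number of events.
#' @param seed integer RNG seed.
#' @return Numeric vector of `n` amplitudes, uV.
#' @export
samplePopulation <- function(spec, n, seed = 1L) {
  if (!inherits(spec, "PopulationSpec"))
    stop("'spec' must be a PopulationSpec", call. = FALSE)
  if (n < 0) stop("'n' must be non-negative", call. = FALSE)
  set.seed(seed)
  .drawAmplitudes(spec, n)
}

.drawAmplitudes <- function(spec, n) {
  if (n == 0) return(numeric(0))
  sdv <- spec$ampCv * spec$ampMeanUv
  amps <- stats::rnorm(n, spec$ampMeanUv, sdv)
  for (i in seq_len(100)) {
    bad <- amps <= 0
    if (!any(bad)) break
    amps[bad] <- stats::rnorm(sum(bad), spec$ampMeanUv, sdv)
  }
  if (any(amps <= 0))
    stop("failed to draw positive amplitudes; check ampCv", call. = FALSE)
  amps
}

#' Cross-frequency amplitude scaling via the circuit model
#'
#' Maps a reference-channel amplitude to all channels using the particle's
#' impedance-change spectrum: amplitude at f equals
#' `refAmpUv * |dZ(f)| / |dZ(f_ref)|`. Bead events are therefore flat
#' across channels; cell and aggregate events decline at high frequency.
#'
#' @param refAmpUv amplitude(s) at the reference frequency, uV.
#' @param particle a [ParticleModel-class].
#' @param circuit an [ElectrodeCircuit-class].
#' @param frequencies frequency grid, Hz.
#' @param referenceFrequencyHz reference frequency; must be in the grid.
#' @return If `refAmpUv` has length 1, a named vector of per-frequency
#'   amplitudes; otherwise a matrix with one row per input amplitude.
#' @export
scaleAcrossFrequencies <- function(refAmpUv, particle,
                                   circuit = ElectrodeCircuit(),
                                   frequencies = defaultFrequencyGrid(),
                                   referenceFrequencyHz = 5e5) {
  if (any(refAmpUv <= 0))
    stop("'refAmpUv' must be positive", call. = FALSE)
  .checkFrequencies(frequencies)
  iref <- .matchFrequency(referenceFrequencyHz, frequencies,
                          "frequency grid")
  dz <- deltaImpedanceMagnitude(circuit, particle, frequencies)
  ratios <- dz / dz[iref]
  out <- outer(refAmpUv, ratios)
  colnames(out) <- .freqColNames("amp_uv", frequencies)
  if (length(refAmpUv) == 1) out[1, ] else out
}

## place n event times uniformly in [margin, duration - margin], rejecting
## candidates closer than 3 pulse widths to an accepted event
.placeEvents <- function(n, durationS, pulseWidthS) {
  if (n == 0) return(numeric(0))
  margin <- 3 * pulseWidthS
  minGap <- 3 * pulseWidthS
  times <- numeric(0)
  attempts <- 0L
  maxAttempts <- 1000L * n
  while (length(times) < n) {
    cand <- stats::runif(1, margin, durationS - margin)
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("could not place ", n, " events without overlap: the ",
           "minimum inter-event gap of 3 pulse widths does not fit in ",
           durationS, " s", call. = FALSE)
    if (!length(times) || min(abs(times - cand)) >= minGap)
      times <- c(times, cand)
  }
  sort(times)
}

#' Generate a multi-frequency trace with ground truth
#'
#' Builds `drift + noise + pulses` on every channel. Each event is a
#' smooth Gaussian bump (sigma = pulseWidthS/4) whose height in each
#' channel is the event's per-frequency amplitude from
#' [scaleAcrossFrequencies()]; event times are uniform random without
#' overlap (3 pulse-width exclusion) and snapped to the sample grid so
#' that the sampled pulse maximum equals the logged amplitude. Output is
#' bit-identical under an identical (config, seed) pair.
#'
#' @param config a [traceConfig()].
#' @param populations list of [populationSpec()] whose weights sum to 1.
#' @param circuit an [ElectrodeCircuit-class] for cross-frequency scaling.
#' @return List with `trace` (a [MultiFrequencyTrace-class]) and `events`
#'   (the ground-truth log: `time_s`, `kind`, one `amp_uv_<hz>` column per
#'   frequency, sorted by time).
#' @export
generateTrace <- function(config, populations,
                          circuit = ElectrodeCircuit()) {
  if (!inherits(config, "TraceConfig"))
    stop("'config' must be a TraceConfig", call. = FALSE)
  if (!length(populations) ||
      !all(vapply(populations, inherits, TRUE, "PopulationSpec")))
    stop("'populations' must be a list of PopulationSpec", call. = FALSE)
  wts <- vapply(populations, `[[`, numeric(1), "weight")
  if (abs(sum(wts) - 1) > 1e-8)
    stop("population weights must sum to 1 (got ", sum(wts), ")",
         call. = FALSE)

  set.seed(config$seed)
  fs <- config$samplingRateHz
  n <- round(config$durationS * fs)
  times <- (seq_len(n) - 1) / fs
  nf <- length(config$frequencies)
  nev <- config$nEvents

  ## ground-truth draws
  kindIdx <- if (nev > 0)
    sample.int(length(populations), nev, replace = TRUE, prob = wts)
  else integer(0)
  refAmps <- numeric(nev)
  for (p in seq_along(populations)) {
    sel <- which(kindIdx == p)
    if (length(sel))
      refAmps[sel] <- .drawAmplitudes(populations[[p]], length(sel))
  }
  evTimes <- .placeEvents(nev, config$durationS, config$pulseWidthS)
  evTimes <- round(evTimes * fs) / fs  # snap to sample grid
  ord <- order(evTimes)

  ## per-population channel scaling ratios
  ratios <- vapply(populations, function(sp) {
    dz <- deltaImpedanceMagnitude(circuit, sp$particle, config$frequencies)
    dz / dz[.matchFrequency(config$referenceFrequencyHz,
                            config$frequencies, "frequency grid")]
  }, numeric(nf))
  ratios <- matrix(ratios, nrow = nf)

  ## baseline + noise
  drift <- config$driftAmplitudeUv *
    sin(2 * pi * times / config$driftPeriodS) +
    config$rampUvPerS * times
  channels <- matrix(0, n, nf)
  for (k in seq_len(nf))
    channels[, k] <- drift +
      (if (config$noiseSigmaUv > 0)
         stats::rnorm(n, 0, config$noiseSigmaUv) else 0)

  ## pulses
  sigmaP <- config$pulseWidthS / 4
  halfWin <- ceiling(5 * sigmaP * fs)
  ampMat <- matrix(0, nev, nf)
  for (e in seq_len(nev)) {
    amp <- refAmps[e] * ratios[, kindIdx[e]]
    ampMat[e, ] <- amp
    ic <- round(evTimes[e] * fs) + 1L
    idx <- max(1L, ic - halfWin):min(n, ic + halfWin)
    bump <- exp(-((times[idx] - evTimes[e])^2) / (2 * sigmaP^2))
    for (k in seq_len(nf))
      channels[idx, k] <- channels[idx, k] + amp[k] * bump
  }

  kinds <- vapply(populations, `[[`, character(1), "kind")
  events <- data.frame(time_s = evTimes[ord],
                       kind = kinds[kindIdx[ord]],
                       stringsAsFactors = FALSE)
  ampCols <- as.data.frame(ampMat[ord, , drop = FALSE])
  names(ampCols) <- .freqColNames("amp_uv", config$frequencies)
  events <- cbind(events, ampCols)

  list(trace = MultiFrequencyTrace(times, channels, config$frequencies),
       events = events)
}

#' Preset experimental samples
#'
#' Event-population mixtures emulating the three measured samples:
#' a pure bead suspension (90% single 2.8 um beads at 2 uV, 10%
#' non-specific bead doublets at 10 uV; 300 events), a pure cell
#' suspension (15 uV; 300 events), and an immuno-magnetically separated
#' mixture (75% bare beads, 25% bead-cell aggregates at 25 uV; 200
#' events). Amplitudes are specified at the 500 kHz / 1 V reference
#' condition; amplitude CVs reflect bead monodispersity (beads 5%,
#' doublets 8%) and cell heterogeneity (cells 20%, aggregates 30%).
#'
#' @param name `"pure_beads"`, `"pure_cells"` or `"mixture"`.
#' @return List of [populationSpec()].
#' @export
presetPopulations <- function(name = c("pure_beads", "pure_cells",
                                       "mixture")) {
  name <- match.arg(name)
  switch(name,
    pure_beads = list(
      populationSpec("bead", 0.9, 2, 0.05),
      populationSpec("bead_doublet", 0.1, 10, 0.08)),
    pure_cells = list(populationSpec("cell", 1.0, 15, 0.20)),
    mixture = list(
      populationSpec("bead", 0.75, 2, 0.05),
      populationSpec("aggregate", 0.25, 25, 0.30)))
}

.presetEventCounts <- c(pure_beads = 300L, pure_cells = 300L,
                        mixture = 200L)

#' Simulate a preset sample
#'
#' @param name preset name (see [presetPopulations()]).
#' @param seed integer RNG seed.
#' @param circuit an [ElectrodeCircuit-class].
#' @param ... overrides passed to [traceConfig()] (e.g. `nEvents`,
#'   `noiseSigmaUv`).
#' @return As [generateTrace()]: list with `trace` and `events`.
#' @examples
#' sim <- presetSample("pure_beads", seed = 1)
#' nrow(sim$events)
#' @export
presetSample <- function(name = c("pure_beads", "pure_cells", "mixture"),
                         seed = 1L, circuit = ElectrodeCircuit(), ...) {
  name <- match.arg(name)
  args <- list(...)
  if (is.null(args$nEvents)) args$nEvents <- .presetEventCounts[[name]]
  args$seed <- seed
  config <- do.call(traceConfig, args)
  generateTrace(config, presetPopulations(name), circuit)
}
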