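#' @import methods
NULL

#' Two-electrode sensor circuit parameters
#'
#' Lumped equivalent-circuit description of the coplanar two-electrode
#' impedance sensor: one double-layer capacitance per electrode/electrolyte
#' interface (the two appear in series, hence the factor 2 in the impedance
#' expression) and the bulk solution resistance between the electrodes.
#'
#' @slot Cdl per-electrode double-layer capacitance, farads.
#' @slot Rs solution resistance, ohms.
#'
#' @seealso [ElectrodeCircuit()], [baselineImpedance()]
#' @exportClass ElectrodeCircuit
setClass("ElectrodeCircuit",
  representation(Cdl = "numeric", Rs = "numeric"))

setValidity("ElectrodeCircuit", function(object) {
  msg <- character()
  if (length(object@Cdl) != 1 || !is.finite(object@Cdl) || object@Cdl <= 0)
    msg <- c(msg, "'Cdl' must be a single positive finite value (farads)")
  if (length(object@Rs) != 1 || !is.finite(object@Rs) || object@Rs <= 0)
    msg <- c(msg, "'Rs' must be a single positive finite value (ohms)")
  if (length(msg)) msg else TRUE
})

#' Construct an ElectrodeCircuit
#'
#' Defaults (1 nF double-layer capacitance, 10 kOhm solution resistance) are
#' plausible for gold microelectrodes in PBS at the device scale used
#' throughout the package; they are tunable, not measured claims.
#'
#' @param C_dl_farads per-electrode double-layer capacitance in farads.
#' @param R_s_ohms solution resistance in ohms.
#' @return An [ElectrodeCircuit-class] object.
#' @examples
#' circ <- ElectrodeCircuit()
#' baselineImpedance(circ, 5e5)
#' @export
ElectrodeCircuit <- function(C_dl_farads = 1e-9, R_s_ohms = 1e4) {
  new("ElectrodeCircuit", Cdl = C_dl_farads, Rs = R_s_ohms)
}

setMethod("show", "ElectrodeCircuit", function(object) {
  cat("ElectrodeCircuit: C_dl =", format(object@Cdl), "F,",
      "R_s =", format(object@Rs), "Ohm\n")
})

#' Per-particle circuit branch
#'
#' The particle transiting the sensing pore is modelled as an occlusion
#' resistance (proportional to particle volume) in parallel with a membrane
#' branch: two membrane capacitances in series with the cytoplasm
#' resistance. For bare beads the membrane branch is open (no membrane
#' capacitance, effectively infinite interior resistivity), so the branch
#' reduces to the occlusion resistance alone.
#'
#' @slot deltaR occlusion resistance, ohms.
#' @slot Cm membrane capacitance in farads; `NA` for beads (open branch).
#' @slot Rc cytoplasm (interior) resistance, ohms.
#' @slot radius particle radius, micrometres.
#' @slot kind one of `"bead"`, `"cell"`, `"aggregate"`.
#'
#' @seealso [beadParticle()], [cellParticle()], [aggregateParticle()]
#' @exportClass ParticleModel
setClass("ParticleModel",
  representation(deltaR = "numeric", Cm = "numeric", Rc = "numeric",
                 radius = "numeric", kind = "character"))

setValidity("ParticleModel", function(object) {
  msg <- character()
  if (length(object@deltaR) != 1 || !is.finite(object@deltaR) ||
      object@deltaR < 0)
    msg <- c(msg, "'deltaR' must be a single non-negative value (ohms)")
  if (length(object@Cm) != 1 || (!is.na(object@Cm) && object@Cm <= 0))
    msg <- c(msg, "'Cm' must be NA (open branch) or a positive value (farads)")
  if (length(object@Rc) != 1 || !is.finite(object@Rc) || object@Rc <= 0)
    msg <- c(msg, "'Rc' must be a single positive value (ohms)")
  if (length(object@radius) != 1 || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "'radius' must be a single positive value (micrometres)")
  if (length(object@kind) != 1 ||
      !object@kind %in% c("bead", "cell", "aggregate"))
    msg <- c(msg, "'kind' must be one of 'bead', 'cell', 'aggregate'")
  if (length(object@kind) == 1 && identical(object@kind, "bead") &&
      !is.na(object@Cm))
    msg <- c(msg, "bead particles must have Cm = NA (membrane branch open)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParticleModel", function(object) {
  cat("ParticleModel <", object@kind, ">: dR =", format(object@deltaR),
      "Ohm, Cm =", if (is.na(object@Cm)) "open" else format(object@Cm),
      if (is.na(object@Cm)) "" else "F,",
      "Rc =", format(object@Rc), "Ohm, radius =",
      format(object@radius), "um\n")
})

#' Multi-frequency lock-in trace
#'
#' Time-aligned demodulated amplitude channels, one per excitation
#' frequency, as delivered by a multi-frequency lock-in amplifier. All
#' channels share one uniform time base; amplitudes are in microvolts.
#'
#' @slot times sample times in seconds (uniform spacing).
#' @slot channels numeric matrix, one column per excitation frequency, uV.
#' @slot frequencies excitation frequencies in Hz (strictly increasing),
#'   one per channel column.
#'
#' @seealso [generateTrace()], [traceTimes()], [traceChannels()]
#' @exportClass MultiFrequencyTrace
setClass("MultiFrequencyTrace",
  representation(times = "numeric", channels = "matrix",
                 frequencies = "numeric"))

setValidity("MultiFrequencyTrace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n < 2) msg <- c(msg, "trace must contain at least 2 samples")
  if (!is.numeric(object@channels))
    msg <- c(msg, "'channels' must be a numeric matrix")
  if (nrow(object@channels) != n)
    msg <- c(msg, "nrow(channels) must equal length(times)")
  if (ncol(object@channels) != length(object@frequencies))
    msg <- c(msg, "ncol(channels) must equal length(frequencies)")
  if (length(object@frequencies) &&
      (any(object@frequencies <= 0) ||
       is.unsorted(object@frequencies, strictly = TRUE)))
    msg <- c(msg, "'frequencies' must be positive and strictly increasing")
  if (n >= 2) {
    dt <- diff(object@times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt))
      msg <- c(msg, "'times' must be uniformly spaced and increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MultiFrequencyTrace
#'
#' @param times sample times, seconds (uniform spacing).
#' @param channels numeric matrix of demodulated amplitudes in uV; one
#'   column per frequency.
#' @param frequencies excitation frequencies, Hz.
#' @return A [MultiFrequencyTrace-class] object.
#' @export
MultiFrequencyTrace <- function(times, channels, frequencies) {
  channels <- as.matrix(channels)
  colnames(channels) <- .freqColNames("amp_uv", frequencies)
  new("MultiFrequencyTrace", times = as.numeric(times), channels = channels,
      frequencies = as.numeric(frequencies))
}

setMethod("show", "MultiFrequencyTrace", function(object) {
  dt <- object@times[2] - object@times[1]
  cat("MultiFrequencyTrace:", length(object@times), "samples @",
      format(1 / dt), "Hz,",
      format(object@times[length(object@times)] - object@times[1]),
      "s span\n  frequencies [Hz]:",
      paste(format(object@frequencies, scientific = FALSE), collapse = ", "),
      "\n")
})

#' @describeIn MultiFrequencyTrace-class sample times in seconds.
#' @param trace a [MultiFrequencyTrace-class].
#' @export
traceTimes <- function(trace) trace@times

#' @describeIn MultiFrequencyTrace-class amplitude matrix (uV), one column
#'   per excitation frequency.
#' @export
traceChannels <- function(trace) trace@channels

#' @describeIn MultiFrequencyTrace-class excitation frequencies in Hz.
#' @export
traceFrequencies <- function(trace) trace@frequencies

#' @describeIn MultiFrequencyTrace-class sampling rate in Hz.
#' @export
samplingRate <- function(trace) 1 / (trace@times[2] - trace@times[1])

#' Extract one frequency channel from a trace
#'
#' @param trace a [MultiFrequencyTrace-class].
#' @param frequency excitation frequency in Hz; must match one of the
#'   trace's channels.
#' @return Numeric vector of amplitudes (uV).
#' @export
traceChannel <- function(trace, frequency) {
  i <- .matchFrequency(frequency, trace@frequencies)
  trace@channels[, i]
}

#' Population gate in two-frequency SNR space
#'
#' Mean and covariance of (SNR at a low frequency, SNR at a high frequency)
#' for a calibration population, defining the Mahalanobis ellipse
#' \eqn{(x-\mu)^T \Sigma^{-1} (x-\mu) \le s^2} used for event
#' classification.
#'
#' @slot name gate label, e.g. `"bead"`, `"cell"`, `"aggregate"`.
#' @slot center length-2 mean vector (SNR at f_low, SNR at f_high).
#' @slot covariance 2x2 sample covariance (symmetric positive-definite).
#' @slot scale number of standard deviations defining the ellipse boundary.
#' @slot frequencies the (f_low, f_high) pair in Hz.
#'
#' @seealso [buildGate()], [classifyEvents()]
#' @exportClass PopulationGate
setClass("PopulationGate",
  representation(name = "character", center = "numeric",
                 covariance = "matrix", scale = "numeric",
                 frequencies = "numeric"))

setValidity("PopulationGate", function(object) {
  msg <- character()
  if (length(object@center) != 2)
    msg <- c(msg, "'center' must have length 2")
  if (!all(dim(object@covariance) == c(2, 2)))
    msg <- c(msg, "'covariance' must be 2x2")
  else {
    if (max(abs(object@covariance - t(object@covariance))) >
        1e-8 * max(abs(object@covariance)))
      msg <- c(msg, "'covariance' must be symmetric")
    ev <- tryCatch(eigen(object@covariance, symmetric = TRUE,
                         only.values = TRUE)$values,
                   error = function(e) NA_real_)
    if (anyNA(ev) || any(ev <= 0))
      msg <- c(msg, paste0("'covariance' must be positive-definite; ",
        "supply more events or regularize the covariance"))
  }
  if (length(object@scale) != 1 || object@scale <= 0)
    msg <- c(msg, "'scale' must be a single positive value")
  if (length(object@frequencies) != 2 || any(object@frequencies <= 0))
    msg <- c(msg, "'frequencies' must be two positive values (Hz)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PopulationGate", function(object) {
  cat("PopulationGate <", object@name, "> @",
      paste(format(object@frequencies, scientific = FALSE), collapse = "/"),
      "Hz\n  center (SNR):",
      paste(format(object@center, digits = 4), collapse = ", "),
      "  scale:", object@scale, "SD\n")
})

#' Gaussian-mixture fit of an amplitude distribution
#'
#' @slot sampleName label of the sample the amplitudes came from.
#' @slot amplitudes the fitted reference-frequency amplitudes (uV).
#' @slot components data.frame with columns `weight`, `mean_uv`, `sd_uv`,
#'   sorted by ascending mean.
#' @slot logLik maximised log-likelihood.
#' @slot bic Bayesian information criterion, conventional smaller-is-better
#'   form (-2 logLik + npar log n).
#' @slot nComponents number of fitted components.
#'
#' @seealso [fitAmplitudeMixture()]
#' @exportClass AmplitudeMixture
setClass("AmplitudeMixture",
  representation(sampleName = "character", amplitudes = "numeric",
                 components = "data.frame", logLik = "numeric",
                 bic = "numeric", nComponents = "integer"))

setMethod("show", "AmplitudeMixture", function(object) {
  cat("AmplitudeMixture <", object@sampleName, ">:",
      object@nComponents, "component(s),",
      length(object@amplitudes), "events, BIC =",
      format(object@bic, digits = 6), "\n")
  print(object@components, digits = 4)
})

#' @describeIn AmplitudeMixture-class component table (weight, mean_uv,
#'   sd_uv) sorted by ascending mean.
#' @param fit an [AmplitudeMixture-class].
#' @export
mixtureComponents <- function(fit) fit@components

## internal: column-name helpers shared by trace/event tables -------------

.freqColNames <- function(prefix, frequencies) {
  paste0(prefix, "_", format(as.numeric(frequencies), scientific = FALSE,
                             trim = TRUE))
}

.matchFrequency <- function(frequency, frequencies, what = "trace") {
  i <- which(abs(frequencies - frequency) <= 1e-6 * frequency)
  if (length(i) != 1)
    stop("frequency ", frequency, " Hz not present in the ", what,
         " (available: ",
         paste(format(frequencies, scientific = FALSE), collapse = ", "),
         ")", call. = FALSE)
  i
}
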