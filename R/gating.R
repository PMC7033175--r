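## Event gating: amplitude-distribution mixture analysis, two-frequency
## SNR covariance ellipses, threshold classification, and the bead/cell
## separability test.

#' Fit a Gaussian mixture to reference-channel amplitudes
#'
#' Maximum-likelihood univariate Gaussian mixture (unequal variances) via
#' mclust, whose model-based hierarchical initialisation is deterministic,
#' so fits are reproducible. Components are reported sorted by ascending
#' mean. The degenerate case of identical amplitudes returns a single
#' zero-sd component.
#'
#' @param amplitudes numeric vector of peak amplitudes, uV (>= 10 values).
#' @param nComponents number of mixture components (1-3).
#' @param seed kept for interface stability; the fit is deterministic and
#'   does not consume randomness.
#' @param sampleName label stored with the fit.
#' @return An [AmplitudeMixture-class].
#' @examples
#' set.seed(1)
#' amps <- c(rnorm(100, 2, 0.3), rnorm(100, 15, 2))
#' fitAmplitudeMixture(amps, 2)
#' @export
fitAmplitudeMixture <- function(amplitudes, nComponents = 2, seed = 1L,
                                sampleName = "sample") {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 10)
    stop("at least 10 amplitudes are required", call. = FALSE)
  if (!nComponents %in% 1:3)
    stop("'nComponents' must be 1, 2 or 3", call. = FALSE)
  if (length(amplitudes) < nComponents)
    stop("fewer points than components", call. = FALSE)
  n <- length(amplitudes)
  if (stats::sd(amplitudes) == 0) {
    comp <- data.frame(weight = 1, mean_uv = amplitudes[1], sd_uv = 0)
    return(new("AmplitudeMixture", sampleName = sampleName,
               amplitudes = amplitudes, components = comp,
               logLik = Inf, bic = -Inf, nComponents = 1L))
  }
  set.seed(seed)
  fit <- mclust::Mclust(amplitudes, G = nComponents, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit))
    stop("mixture fit failed for ", nComponents, " component(s)",
         call. = FALSE)
  p <- fit$parameters
  sds <- sqrt(p$variance$sigmasq)
  if (length(sds) == 1) sds <- rep(sds, fit$G)
  comp <- data.frame(weight = p$pro, mean_uv = as.numeric(p$mean),
                     sd_uv = sds)
  comp <- comp[order(comp$mean_uv), , drop = FALSE]
  rownames(comp) <- NULL
  ## mclust reports BIC as 2*logLik - npar*log(n); convert to the
  ## conventional smaller-is-better form
  new("AmplitudeMixture", sampleName = sampleName,
      amplitudes = amplitudes, components = comp,
      logLik = fit$loglik, bic = -as.numeric(fit$bic),
      nComponents = as.integer(fit$G))
}

#' Compare mixture-component counts by BIC
#'
#' Fits each candidate component count and reports the BIC (conventional
#' smaller-is-better form); used to test for bimodality of an amplitude
#' distribution (2 components beating 1).
#'
#' @inheritParams fitAmplitudeMixture
#' @param candidates integer vector of component counts to compare.
#' @return List with `bic` (named numeric, one entry per candidate),
#'   `best` (component count with smallest BIC) and `fits` (the
#'   [AmplitudeMixture-class] objects).
#' @export
selectMixtureComponents <- function(amplitudes, candidates = 1:2,
                                    seed = 1L, sampleName = "sample") {
  fits <- lapply(candidates, function(g)
    fitAmplitudeMixture(amplitudes, g, seed, sampleName))
  bic <- vapply(fits, function(f) f@bic, numeric(1))
  names(bic) <- as.character(candidates)
  names(fits) <- as.character(candidates)
  list(bic = bic, best = candidates[which.min(bic)], fits = fits)
}

#' Build a population gate in two-frequency SNR space
#'
#' Computes the mean and sample covariance of (SNR at `fLow`, SNR at
#' `fHigh`) over a calibration sample's events; the gate is the
#' Mahalanobis ellipse at `scale` standard deviations.
#'
#' @param events event data.frame with `snr_<hz>` columns (from
#'   [detectPeaks()]).
#' @param fLow,fHigh the two gating frequencies, Hz.
#' @param scale ellipse boundary in standard deviations (default 1).
#' @param name gate label.
#' @return A [PopulationGate-class].
#' @export
buildGate <- function(events, fLow = 5e5, fHigh = 2e7, scale = 1,
                      name = "gate") {
  x <- .snrMatrix(events, fLow, fHigh)
  if (nrow(x) < 3)
    stop("at least 3 events are required to build a gate", call. = FALSE)
  ctr <- colMeans(x)
  cv <- stats::cov(x)
  ok <- tryCatch({ chol(cv); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("singular SNR covariance; supply more events or regularize ",
         "the covariance", call. = FALSE)
  new("PopulationGate", name = name, center = as.numeric(ctr),
      covariance = cv, scale = scale,
      frequencies = c(fLow, fHigh))
}

.snrMatrix <- function(events, fLow, fHigh) {
  freqs <- .eventFrequencies(events)
  cl <- .freqColNames("snr", freqs[.matchFrequency(fLow, freqs,
                                                   "event table")])
  ch <- .freqColNames("snr", freqs[.matchFrequency(fHigh, freqs,
                                                   "event table")])
  if (!all(c(cl, ch) %in% names(events)))
    stop("event table lacks SNR columns for the gating frequencies",
         call. = FALSE)
  cbind(low = events[[cl]], high = events[[ch]])
}

#' Mahalanobis distance of events to a gate centre
#'
#' @param gate a [PopulationGate-class].
#' @param events event data.frame with matching `snr_<hz>` columns.
#' @return Numeric vector of Mahalanobis distances (in SD units); an
#'   event is inside the gate when its distance is <= `gate@scale`.
#' @export
gateDistance <- function(gate, events) {
  x <- .snrMatrix(events, gate@frequencies[1], gate@frequencies[2])
  sqrt(stats::mahalanobis(x, gate@center, gate@covariance))
}

#' @rdname gateDistance
#' @return `inGate`: logical vector of gate membership.
#' @export
inGate <- function(gate, events) gateDistance(gate, events) <= gate@scale

#' Classify events against population gates
#'
#' Rules: an event inside the bead gate is a bead (the bead gate has
#' priority, so mixture events overlapping the bead ellipse are not
#' counted as aggregates); otherwise, among the remaining gates the event
#' is inside, the one with the smallest Mahalanobis distance wins; an
#' event inside no gate is assigned to the nearest gate by Mahalanobis
#' distance. Every event receives exactly one label.
#'
#' @param events event data.frame (from [detectPeaks()]).
#' @param beadGate,aggregateGate required [PopulationGate-class] objects.
#' @param cellGate optional [PopulationGate-class].
#' @return List with `events` (input plus a `label` column) and `counts`
#'   (named integer vector over the provided gate labels).
#' @export
classifyEvents <- function(events, beadGate, aggregateGate,
                           cellGate = NULL) {
  if (missing(beadGate) || missing(aggregateGate) ||
      !is(beadGate, "PopulationGate") ||
      !is(aggregateGate, "PopulationGate"))
    stop("bead and aggregate gates are required", call. = FALSE)
  gates <- list(bead = beadGate, aggregate = aggregateGate)
  if (!is.null(cellGate)) gates$cell <- cellGate
  labels <- names(gates)
  counts <- stats::setNames(integer(length(gates)), labels)
  if (nrow(events) == 0) {
    events$label <- character(0)
    return(list(events = events, counts = counts))
  }
  d <- vapply(gates, gateDistance, numeric(nrow(events)), events = events)
  d <- matrix(d, nrow = nrow(events),
              dimnames = list(NULL, labels))
  scales <- vapply(gates, function(g) g@scale, numeric(1))
  inside <- sweep(d, 2, scales, "<=")
  lab <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (inside[i, "bead"]) {
      lab[i] <- "bead"
    } else if (any(inside[i, ])) {
      cand <- labels[inside[i, ]]
      lab[i] <- cand[which.min(d[i, cand])]
    } else {
      lab[i] <- labels[which.min(d[i, ])]
    }
  }
  events$label <- lab
  tb <- table(factor(lab, levels = labels))
  counts[] <- as.integer(tb)
  list(events = events, counts = counts)
}

#' One-dimensional amplitude-threshold classification
#'
#' The simple alternative to ellipse gating: events whose
#' reference-channel amplitude exceeds `thresholdUv` (default 10 uV) are
#' labelled aggregates, the rest beads.
#'
#' @param events event data.frame with `amp_uv_<hz>` columns.
#' @param thresholdUv amplitude threshold, uV.
#' @param referenceFrequencyHz reference channel, Hz.
#' @return List with `events` (plus `label` column) and `counts` (named
#'   integer: bead, aggregate).
#' @export
thresholdClassify <- function(events, thresholdUv = 10,
                              referenceFrequencyHz = 5e5) {
  counts <- c(bead = 0L, aggregate = 0L)
  if (nrow(events) == 0) {
    events$label <- character(0)
    return(list(events = events, counts = counts))
  }
  amps <- referenceAmplitudes(events, referenceFrequencyHz)
  lab <- ifelse(amps > thresholdUv, "aggregate", "bead")
  events$label <- lab
  tb <- table(factor(lab, levels = names(counts)))
  counts[] <- as.integer(tb)
  list(events = events, counts = counts)
}

#' Welch two-sample comparison of amplitude populations
#'
#' Unequal-variance (Welch) t-test on reference-channel amplitudes of two
#' samples, the separability check between e.g. the bead and cell
#' populations.
#'
#' @param ampsA,ampsB numeric amplitude vectors, uV (>= 2 values each).
#' @return List with `statistic`, `p.value`, `mean_a`, `mean_b`,
#'   `method`.
#' @export
comparePopulations <- function(ampsA, ampsB) {
  if (length(ampsA) < 2 || length(ampsB) < 2)
    stop("at least 2 observations per sample are required", call. = FALSE)
  tt <- stats::t.test(ampsA, ampsB, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       mean_a = mean(ampsA), mean_b = mean(ampsB), method = tt$method)
}
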