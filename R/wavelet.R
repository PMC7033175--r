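## Maximal-overlap discrete wavelet transform (MODWT) and the
## detrend/denoise chain built on it.
##
## The MODWT is shift-invariant and defined for any series length, which
## suits event traces whose length is not a power of two. Filters are the
## standard unit-norm DWT filters rescaled by 1/sqrt(2); the pyramid and
## its inverse are the usual circular-convolution recursions (implemented
## in C, src/modwt.cpp). To avoid circular-boundary artefacts on
## non-periodic traces (slow drift does not wrap), series are
## reflection-extended to twice their length before the transform and
## truncated after reconstruction.

## standard orthonormal scaling (lowpass) filters
.scalingFilters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  sym8 = c(-0.0033824159510061256, -0.0005421323317911481,
           0.03169508781149298, 0.007607487324917605,
           -0.1432942383508097, -0.061273359067658524,
           0.4813596512583722, 0.7771857517005235,
           0.3644418948353314, -0.05194583810770904,
           -0.027219029917056003, 0.049137179673607506,
           0.003808752013890615, -0.01495225833704823,
           -0.0003029205147213668, 0.0018899503327594609))

.waveletFilters <- function(wavelet) {
  g <- .scalingFilters[[wavelet]]
  if (is.null(g))
    stop("unsupported wavelet '", wavelet, "'; available: ",
         paste(names(.scalingFilters), collapse = ", "), call. = FALSE)
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)    # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2)) # MODWT rescaling
}

#' Wavelet filter configuration
#'
#' Settings for the detrend/denoise chain. `level` is the decomposition
#' depth; `NULL` selects it from the pulse width so that the coarsest
#' approximation scale is about 100 pulse widths (ceiling of
#' log2(100 x pulse width in samples)). The deep level matters: the
#' removed smooth at a scale of only ~10 pulse widths still carries
#' several percent of each pulse's height, biasing recovered amplitudes.
#' Thresholding uses the universal threshold sigma * sqrt(2 log N)
#' (scaled per MODWT level), sigma estimated from the finest-level
#' details by MAD; `"soft"` is the chain default because the levels it is
#' applied to carry no pulse energy (see [filterTrace()]) and soft
#' shrinkage leaves the smallest super-threshold residue.
#'
#' @param wavelet wavelet family name; `"sym8"` (default) or `"haar"`.
#' @param level integer decomposition level, or `NULL` to derive it from
#'   the pulse width at filter time.
#' @param thresholdRule `"universal"` or `"none"` (pass-through).
#' @param thresholdMode `"soft"` or `"hard"`.
#' @return A list of class `FilterConfig`.
#' @export
filterConfig <- function(wavelet = "sym8", level = NULL,
                         thresholdRule = c("universal", "none"),
                         thresholdMode = c("soft", "hard")) {
  .waveletFilters(wavelet)
  if (!is.null(level) && (level < 1 || level != round(level)))
    stop("'level' must be a positive integer", call. = FALSE)
  structure(list(wavelet = wavelet, level = level,
                 thresholdRule = match.arg(thresholdRule),
                 thresholdMode = match.arg(thresholdMode)),
            class = "FilterConfig")
}

.resolveLevel <- function(cfg, n, samplingRate = NULL, pulseWidthS = 1e-3) {
  level <- cfg$level
  if (is.null(level)) {
    if (is.null(samplingRate))
      stop("either an explicit 'level' or a sampling rate is required",
           call. = FALSE)
    level <- max(1L, ceiling(log2(100 * pulseWidthS * samplingRate)))
  }
  if (n < 2^level)
    stop("series of length ", n, " is too short for decomposition level ",
         level, " (need at least 2^level samples)", call. = FALSE)
  as.integer(level)
}

#' Forward MODWT
#'
#' @param x numeric series.
#' @param level decomposition depth J (series must have >= 2^J samples).
#' @param wavelet filter name (`"sym8"` or `"haar"`).
#' @param reflect extend the series by reflection to suppress circular
#'   boundary artefacts (default `TRUE`).
#' @return List with `W` (list of detail coefficient vectors, levels
#'   1..J), `V` (coarsest approximation), and bookkeeping needed by
#'   [imodwt()]. Coefficient vectors cover the (possibly extended)
#'   series.
#' @seealso [imodwt()]
#' @examples
#' x <- sin(seq(0, 4 * pi, length.out = 128))
#' max(abs(imodwt(modwt(x, 3)) - x)) < 1e-10
#' @export
modwt <- function(x, level, wavelet = "sym8", reflect = TRUE) {
  filt <- .waveletFilters(wavelet)
  n0 <- length(x)
  if (n0 < 2^level)
    stop("series too short for level ", level, call. = FALSE)
  v <- if (reflect) c(x, rev(x)) else as.numeric(x)
  dec <- .modwtForwardCpp(v, filt$g, filt$h, as.integer(level))
  list(W = dec$W, V = dec$V, level = as.integer(level), wavelet = wavelet,
       reflect = reflect, n = n0)
}

#' Inverse MODWT
#'
#' @param w a decomposition from [modwt()] (coefficients may be modified
#'   before inversion, e.g. thresholded or zeroed).
#' @return Numeric series of the original length.
#' @export
imodwt <- function(w) {
  filt <- .waveletFilters(w$wavelet)
  v <- .modwtInverseCpp(w$W, w$V, filt$g, filt$h)
  v[seq_len(w$n)]
}

## sigma estimate from finest-level details: MAD/0.6745 with the sqrt(2)
## factor restoring signal-domain units (MODWT level-1 white-noise
## coefficients have sd sigma/sqrt(2)).
.sigmaFromW1 <- function(w1) {
  sqrt(2) * stats::mad(w1, constant = 1 / 0.6745)
}

#' Robust noise estimate from finest wavelet details
#'
#' Median-absolute-deviation estimate of the white-noise standard
#' deviation, computed on the finest-scale MODWT details so that sparse
#' transit pulses and slow drift do not inflate it.
#'
#' @param channel numeric series (uV).
#' @param wavelet filter name.
#' @return Estimated noise sigma in uV (0 for an all-zero series).
#' @export
estimateNoiseSigma <- function(channel, wavelet = "sym8") {
  if (length(channel) == 0)
    stop("cannot estimate noise on an empty series", call. = FALSE)
  if (length(channel) < 2 || all(channel == 0)) return(0)
  w <- modwt(channel, level = 1L, wavelet = wavelet)
  .sigmaFromW1(w$W[[1]])
}

#' Wavelet baseline-drift removal
#'
#' Decomposes the channel to the configured level and reconstructs from
#' the detail coefficients only (the coarsest approximation — the slow
#' baseline — is zeroed). Millisecond transit pulses live in the fine
#' details and pass through essentially unchanged; drift components far
#' slower than the coarsest scale are removed.
#'
#' @param channel numeric series (uV).
#' @param cfg a [filterConfig()].
#' @param samplingRate samples per second; needed only when `cfg$level`
#'   is `NULL`.
#' @param pulseWidthS nominal transit-pulse duration in seconds (used for
#'   automatic level selection).
#' @return Detrended series, same length as the input.
#' @export
waveletDetrend <- function(channel, cfg = filterConfig(),
                           samplingRate = NULL, pulseWidthS = 1e-3) {
  level <- .resolveLevel(cfg, length(channel), samplingRate, pulseWidthS)
  w <- modwt(channel, level, cfg$wavelet)
  w$V[] <- 0
  imodwt(w)
}

## threshold detail levels 1..maxLevel of a decomposition
.thresholdDetails <- function(w, mode, nOrig, maxLevel = NULL) {
  sigma <- .sigmaFromW1(w$W[[1]])
  if (sigma == 0) return(w)
  jmax <- if (is.null(maxLevel)) w$level else min(maxLevel, w$level)
  for (j in seq_len(jmax)) {
    lambda <- sigma * sqrt(2 * log(nOrig)) * 2^(-j / 2)
    wj <- w$W[[j]]
    if (mode == "hard") {
      wj[abs(wj) < lambda] <- 0
    } else {
      wj <- sign(wj) * pmax(abs(wj) - lambda, 0)
    }
    w$W[[j]] <- wj
  }
  w
}

#' Wavelet denoising
#'
#' Universal-threshold wavelet shrinkage: detail coefficients below
#' \eqn{\sigma\sqrt{2\log N}} (scaled per MODWT level) are shrunk (soft)
#' or zeroed (hard), with \eqn{\sigma} estimated from the finest-level
#' details by MAD. By default all detail levels are thresholded; pass
#' `maxLevel` to restrict shrinkage to the finest levels, which is what
#' the event-detection chain does so that detail scales carrying pulse
#' energy are never attenuated (see [filterTrace()]). With
#' `thresholdRule = "none"` the input is returned unchanged.
#'
#' @inheritParams waveletDetrend
#' @param maxLevel threshold only levels 1..maxLevel (`NULL` = all).
#' @return Denoised series, same length as the input.
#' @export
waveletDenoise <- function(channel, cfg = filterConfig(),
                           samplingRate = NULL, pulseWidthS = 1e-3,
                           maxLevel = NULL) {
  if (cfg$thresholdRule == "none") return(channel)
  level <- .resolveLevel(cfg, length(channel), samplingRate, pulseWidthS)
  w <- modwt(channel, level, cfg$wavelet)
  w <- .thresholdDetails(w, cfg$thresholdMode, length(channel), maxLevel)
  imodwt(w)
}

## detail levels whose scale lies below the pulse core (Gaussian sigma of
## the pulse in samples); these carry essentially no pulse energy.
.subPulseLevels <- function(samplingRate, pulseWidthS) {
  sigmaSamples <- pulseWidthS / 4 * samplingRate
  max(1L, floor(log2(sigmaSamples)))
}

#' Filter all channels of a trace (detrend + denoise)
#'
#' One decomposition per channel serves three purposes: the slow baseline
#' (coarsest approximation) is removed; the finest detail levels — those
#' at scales below the pulse core, which hold about half of the
#' white-noise power but essentially none of the pulse energy — are
#' shrunk by the universal threshold; and the white-noise sigma is
#' estimated from the finest-level details. The sigma reported is the
#' post-detrend, pre-denoise value (detrending does not touch the finest
#' details); it is the denominator used for per-event SNR and for the
#' detection threshold.
#'
#' @param trace a [MultiFrequencyTrace-class].
#' @param cfg a [filterConfig()].
#' @param pulseWidthS nominal transit-pulse duration, seconds.
#' @return List with `trace` (filtered [MultiFrequencyTrace-class]) and
#'   `noiseSigma` (named numeric, uV per channel).
#' @export
filterTrace <- function(trace, cfg = filterConfig(), pulseWidthS = 1e-3) {
  fs <- samplingRate(trace)
  ch <- traceChannels(trace)
  level <- .resolveLevel(cfg, nrow(ch), fs, pulseWidthS)
  maxLevel <- .subPulseLevels(fs, pulseWidthS)
  out <- ch
  sigmas <- numeric(ncol(ch))
  for (k in seq_len(ncol(ch))) {
    w <- modwt(ch[, k], level, cfg$wavelet)
    sigmas[k] <- .sigmaFromW1(w$W[[1]])
    w$V[] <- 0
    if (cfg$thresholdRule != "none")
      w <- .thresholdDetails(w, cfg$thresholdMode, nrow(ch), maxLevel)
    out[, k] <- imodwt(w)
  }
  names(sigmas) <- .freqColNames("sigma_uv", traceFrequencies(trace))
  list(trace = MultiFrequencyTrace(traceTimes(trace), out,
                                   traceFrequencies(trace)),
       noiseSigma = sigmas)
}
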