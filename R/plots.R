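## Figure-style summaries: amplitude histograms per sample and the
## two-frequency SNR scatter with population ellipses.

#' Peak-amplitude distributions by sample
#'
#' Percentage histograms of reference-channel peak amplitudes, one curve
#' per sample, with the aggregate amplitude threshold marked.
#'
#' @param ampsBySample named list of numeric amplitude vectors (uV).
#' @param binwidthUv histogram bin width, uV.
#' @param thresholdUv vertical threshold marker, uV (NULL to omit).
#' @return A ggplot object.
#' @export
plotAmplitudeDistributions <- function(ampsBySample, binwidthUv = 1,
                                       thresholdUv = 10) {
  df <- do.call(rbind, lapply(names(ampsBySample), function(nm)
    data.frame(sample = nm, amp_uv = ampsBySample[[nm]])))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$amp_uv,
                                        colour = .data$sample)) +
    ggplot2::geom_freqpoly(ggplot2::aes(
      y = ggplot2::after_stat(.data$density) * 100 * binwidthUv),
      binwidth = binwidthUv, linewidth = 0.7) +
    ggplot2::labs(x = "Peak amplitude [uV]", y = "Percentage of events",
                  colour = NULL) +
    ggplot2::theme_classic()
  if (!is.null(thresholdUv))
    p <- p + ggplot2::geom_vline(xintercept = thresholdUv,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' Two-frequency SNR scatter with gate ellipses
#'
#' Events of each sample plotted at (SNR at `fLow`, SNR at `fHigh`),
#' with the population gates drawn as Mahalanobis ellipses at their
#' configured scale.
#'
#' @param eventsBySample named list of event data.frames (with
#'   `snr_<hz>` columns).
#' @param gates list of [PopulationGate-class] objects to draw.
#' @param fLow,fHigh axis frequencies, Hz.
#' @param nEllipse points per ellipse outline.
#' @return A ggplot object.
#' @export
plotSnrScatter <- function(eventsBySample, gates = list(), fLow = 5e5,
                           fHigh = 2e7, nEllipse = 120) {
  df <- do.call(rbind, lapply(names(eventsBySample), function(nm) {
    x <- .snrMatrix(eventsBySample[[nm]], fLow, fHigh)
    data.frame(sample = nm, snr_low = x[, 1], snr_high = x[, 2])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$snr_low,
                                        y = .data$snr_high,
                                        colour = .data$sample)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = sprintf("SNR @ %s Hz", format(fLow, scientific = FALSE)),
      y = sprintf("SNR @ %s Hz", format(fHigh, scientific = FALSE)),
      colour = NULL) +
    ggplot2::theme_classic()
  if (length(gates)) {
    ell <- do.call(rbind, lapply(gates, function(g) {
      theta <- seq(0, 2 * pi, length.out = nEllipse)
      circ <- rbind(cos(theta), sin(theta)) * g@scale
      ch <- chol(g@covariance)
      pts <- t(t(ch) %*% circ + g@center)
      data.frame(gate = g@name, snr_low = pts[, 1], snr_high = pts[, 2])
    }))
    p <- p + ggplot2::geom_path(
      data = ell, ggplot2::aes(x = .data$snr_low, y = .data$snr_high,
                               group = .data$gate),
      colour = "grey30", inherit.aes = FALSE, linewidth = 0.5)
  }
  p
}
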