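## CSV persistence for traces and event tables.
##
## Trace schema (wide): time_s, amp_uv_<hz> per frequency.
## Event schema: time_s [, kind], amp_uv_<hz>..., [snr_<hz>...], [label].

#' Write / read a multi-frequency trace as wide CSV
#'
#' @param trace a [MultiFrequencyTrace-class].
#' @param path CSV path.
#' @return `writeTrace`: `path`, invisibly. `readTrace`: a
#'   [MultiFrequencyTrace-class] (frequencies recovered from the column
#'   names).
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "MultiFrequencyTrace"))
  df <- data.table::data.table(time_s = traceTimes(trace))
  ch <- traceChannels(trace)
  for (k in seq_len(ncol(ch))) df[[colnames(ch)[k]]] <- ch[, k]
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  ampCols <- grep("^amp_uv_", names(df), value = TRUE)
  if (!"time_s" %in% names(df) || !length(ampCols))
    stop("'", path, "' is not a trace CSV (need time_s and amp_uv_<hz> ",
         "columns)", call. = FALSE)
  freqs <- as.numeric(sub("^amp_uv_", "", ampCols))
  ord <- order(freqs)
  MultiFrequencyTrace(df$time_s,
                      as.matrix(df[, ampCols[ord], drop = FALSE]),
                      freqs[ord])
}

#' Write / read an event table as CSV
#'
#' Used both for ground-truth event logs (with a `kind` column) and for
#' detected-event tables (with `snr_<hz>` columns and, after
#' classification, a `label` column).
#'
#' @param events event data.frame.
#' @param path CSV path.
#' @return `writeEvents`: `path`, invisibly. `readEvents`: data.frame.
#' @export
writeEvents <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(df))
    stop("'", path, "' is not an events CSV (no time_s column)",
         call. = FALSE)
  df
}

#' Serialize a population gate to a plain list (for JSON)
#'
#' @param gate a [PopulationGate-class].
#' @return Named list of gate parameters.
#' @export
gateToList <- function(gate) {
  list(name = gate@name, center = as.numeric(gate@center),
       covariance = unclass(gate@covariance),
       scale = gate@scale, frequencies_hz = as.numeric(gate@frequencies))
}

#' Serialize a mixture fit to a plain list (for JSON)
#'
#' @param fit an [AmplitudeMixture-class].
#' @return Named list of fit parameters.
#' @export
mixtureToList <- function(fit) {
  list(sample = fit@sampleName, n_components = fit@nComponents,
       components = fit@components, log_lik = fit@logLik, bic = fit@bic,
       n_events = length(fit@amplitudes))
}
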