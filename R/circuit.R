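## Equivalent-circuit forward model of the two-electrode sensor.
##
## Total impedance with a particle between the electrodes:
##   Z(f) = 2/(j w C_dl) + R_s + dR || (2/(j w C_m) + R_c),   w = 2 pi f
## The factor 2 on both capacitive terms reflects the two
## electrode/electrolyte interfaces (and two membrane crossings) in series.

#' Default particle models
#'
#' Standard particle parameterisations used throughout the package. The
#' bead is a 2.8 um (diameter) superparamagnetic bead: no membrane
#' capacitance, effectively infinite interior resistivity, so its circuit
#' branch is the occlusion resistance alone and its impedance change is
#' flat in frequency. The cell has twice the bead radius (hence 8x the
#' volume and 8x the occlusion resistance, by the volume law) plus a
#' membrane branch whose capacitance shorts progressively above ~1 MHz,
#' giving the characteristic high-frequency decline of the cell impedance
#' change. An aggregate is modelled as a cell plus `nBeads` bead volumes
#' (occlusion resistance via the volume law) retaining the cell's membrane
#' branch.
#'
#' @param deltaR occlusion resistance, ohms.
#' @param radiusUm particle radius, micrometres.
#' @param Rc interior resistance, ohms (nominal for beads: branch is open).
#' @param Cm membrane capacitance, farads.
#' @param nBeads number of beads bound to the cell.
#' @param cell,bead component particle models for the aggregate.
#' @return A [ParticleModel-class].
#' @examples
#' deltaImpedanceMagnitude(ElectrodeCircuit(), beadParticle(), 5e5)
#' frequencyResponseCurve(ElectrodeCircuit(), cellParticle(),
#'                        defaultFrequencyGrid())
#' @export
beadParticle <- function(deltaR = 100, radiusUm = 1.4, Rc = 1e9) {
  new("ParticleModel", deltaR = deltaR, Cm = NA_real_, Rc = Rc,
      radius = radiusUm, kind = "bead")
}

#' @rdname beadParticle
#' @export
cellParticle <- function(deltaR = 800, Cm = 100e-12, Rc = 400,
                         radiusUm = 2.8) {
  new("ParticleModel", deltaR = deltaR, Cm = Cm, Rc = Rc,
      radius = radiusUm, kind = "cell")
}

#' @rdname beadParticle
#' @export
aggregateParticle <- function(nBeads = 2, cell = cellParticle(),
                              bead = beadParticle()) {
  if (nBeads < 1) stop("'nBeads' must be at least 1", call. = FALSE)
  volRatio <- 1 + nBeads * (bead@radius / cell@radius)^3
  new("ParticleModel",
      deltaR = occlusionResistance(cell@deltaR, volRatio^(1 / 3)),
      Cm = cell@Cm, Rc = cell@Rc,
      radius = cell@radius * volRatio^(1 / 3), kind = "aggregate")
}

#' Default excitation frequency grid
#'
#' The five demodulation frequencies used for multi-frequency acquisition:
#' 300 kHz, 500 kHz, 1 MHz, 5 MHz and 20 MHz.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
defaultFrequencyGrid <- function() c(3e5, 5e5, 1e6, 5e6, 2e7)

.checkFrequencies <- function(f) {
  if (length(f) == 0)
    stop("frequency grid must contain at least one frequency", call. = FALSE)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("frequencies must be positive and finite (Hz)", call. = FALSE)
  if (is.unsorted(f, strictly = TRUE) && length(f) > 1)
    stop("frequency grid must be strictly increasing", call. = FALSE)
  invisible(f)
}

#' Baseline impedance of the empty sensor
#'
#' Impedance across the electrodes with no particle present: the two
#' double-layer capacitances in series with the solution resistance,
#' \eqn{Z_0(f) = 2/(j 2\pi f C_{dl}) + R_s}. Its magnitude decreases
#' monotonically with frequency and tends to \eqn{R_s} as the capacitors
#' short at high frequency.
#'
#' @param circuit an [ElectrodeCircuit-class].
#' @param f excitation frequency (or vector of frequencies), Hz.
#' @return Complex impedance in ohms (vectorised over `f`).
#' @export
baselineImpedance <- function(circuit, f) {
  stopifnot(is(circuit, "ElectrodeCircuit"))
  validObject(circuit)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be positive and finite (Hz)", call. = FALSE)
  2 / (1i * 2 * pi * f * circuit@Cdl) + circuit@Rs
}

## impedance of the particle branch: dR || (2/(j w Cm) + Rc);
## beads have an open membrane branch, so the branch is dR alone.
.particleBranch <- function(particle, f) {
  if (is.na(particle@Cm))
    return(rep(complex(real = particle@deltaR), length(f)))
  membrane <- 2 / (1i * 2 * pi * f * particle@Cm) + particle@Rc
  particle@deltaR * membrane / (particle@deltaR + membrane)
}

#' Total impedance with a particle in the pore
#'
#' \eqn{Z(f) = 2/(j\omega C_{dl}) + R_s + \Delta R \parallel
#' (2/(j\omega C_m) + R_c)}. For beads the membrane branch is open and the
#' particle contributes \eqn{\Delta R} alone.
#'
#' @inheritParams baselineImpedance
#' @param particle a [ParticleModel-class].
#' @return Complex impedance in ohms (vectorised over `f`).
#' @export
totalImpedance <- function(circuit, particle, f) {
  stopifnot(is(particle, "ParticleModel"))
  validObject(particle)
  baselineImpedance(circuit, f) + .particleBranch(particle, f)
}

#' Impedance-change magnitude caused by a transiting particle
#'
#' \eqn{|\Delta Z(f)| = |Z(f) - Z_0(f)|}, the quantity plotted as the
#' per-frequency response of a particle. Beads are flat in frequency
#' (purely resistive branch); cells decline once the membrane capacitance
#' begins to short, with the default parameters placing the corner near
#' 1 MHz.
#'
#' @inheritParams totalImpedance
#' @return Magnitude in ohms (vectorised over `f`).
#' @export
deltaImpedanceMagnitude <- function(circuit, particle, f) {
  stopifnot(is(circuit, "ElectrodeCircuit"), is(particle, "ParticleModel"))
  validObject(circuit); validObject(particle)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be positive and finite (Hz)", call. = FALSE)
  Mod(.particleBranch(particle, f))
}

#' Volume-proportional occlusion resistance scaling
#'
#' The occlusion resistance is proportional to particle volume, so a
#' particle with `radiusRatio` times the reference radius has
#' `radiusRatio^3` times the reference occlusion resistance. A particle of
#' twice the radius therefore shows an 8-fold larger low-frequency
#' impedance change.
#'
#' @param referenceDeltaR occlusion resistance of the reference particle,
#'   ohms.
#' @param radiusRatio ratio of particle radius to reference radius.
#' @return Scaled occlusion resistance, ohms.
#' @export
occlusionResistance <- function(referenceDeltaR, radiusRatio) {
  if (any(!is.finite(referenceDeltaR)) || any(referenceDeltaR <= 0))
    stop("'referenceDeltaR' must be positive (ohms)", call. = FALSE)
  if (any(!is.finite(radiusRatio)) || any(radiusRatio <= 0))
    stop("'radiusRatio' must be positive", call. = FALSE)
  referenceDeltaR * radiusRatio^3
}

#' Frequency-response curve of a particle
#'
#' Evaluates [deltaImpedanceMagnitude()] over a frequency grid.
#'
#' @inheritParams totalImpedance
#' @param frequencies frequency grid in Hz (strictly increasing).
#' @return data.frame with columns `frequency_hz`, `delta_z_ohms`, in grid
#'   order.
#' @export
frequencyResponseCurve <- function(circuit, particle,
                                   frequencies = defaultFrequencyGrid()) {
  .checkFrequencies(frequencies)
  data.frame(frequency_hz = frequencies,
             delta_z_ohms = deltaImpedanceMagnitude(circuit, particle,
                                                    frequencies))
}

#' Write a frequency-response curve as CSV
#'
#' @param curve data.frame from [frequencyResponseCurve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFrequencyResponseCsv <- function(curve, path) {
  data.table::fwrite(curve, path)
  invisible(path)
}

#' Read circuit/grid configuration from YAML or JSON
#'
#' Field names carry explicit SI units: `C_dl_farads`, `R_s_ohms`, and a
#' `frequencies_hz` vector; an optional `particles` section may override
#' the default particle parameters (`bead`/`cell` blocks with
#' `delta_R_ohms`, `C_m_farads`, `R_c_ohms`, `radius_um`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return List with elements `circuit` ([ElectrodeCircuit-class]),
#'   `frequencies` (Hz) and `particles` (named list of
#'   [ParticleModel-class]).
#' @export
readCircuitConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  circuit <- ElectrodeCircuit(
    C_dl_farads = cfg$C_dl_farads %||% 1e-9,
    R_s_ohms = cfg$R_s_ohms %||% 1e4)
  frequencies <- as.numeric(cfg$frequencies_hz %||% defaultFrequencyGrid())
  .checkFrequencies(frequencies)
  p <- cfg$particles
  particles <- list(
    bead = beadParticle(
      deltaR = p$bead$delta_R_ohms %||% 100,
      radiusUm = p$bead$radius_um %||% 1.4),
    cell = cellParticle(
      deltaR = p$cell$delta_R_ohms %||% 800,
      Cm = p$cell$C_m_farads %||% 100e-12,
      Rc = p$cell$R_c_ohms %||% 400,
      radiusUm = p$cell$radius_um %||% 2.8))
  particles$aggregate <- aggregateParticle(
    nBeads = p$aggregate$n_beads %||% 2,
    cell = particles$cell, bead = particles$bead)
  list(circuit = circuit, frequencies = frequencies, particles = particles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
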