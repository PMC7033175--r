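# Independent oracles and shared fixtures.

# Circuit oracle: reciprocal-sum formulation of the sensor impedance,
# coded independently of the package's parallel-combination helper.
oracleImpedance <- function(Cdl, Rs, dR, Cm, Rc, f) {
  w <- 2 * pi * f
  zb <- 2 / (1i * w * Cdl) + Rs
  if (is.null(dR)) return(zb)
  zp <- if (is.na(Cm)) dR + 0i else 1 / (1 / dR + 1 / (2 / (1i * w * Cm) + Rc))
  zb + zp
}

# Brute-force MODWT (direct Percival-Walden recursions, plain R loops,
# no boundary extension) for tiny series.
bruteModwt <- function(x, level, wavelet = "haar") {
  g0 <- list(haar = c(1, 1) / sqrt(2),
             sym8 = impedCyto:::.scalingFilters$sym8)[[wavelet]]
  L <- length(g0)
  h0 <- rev(g0) * (-1)^(seq_len(L) - 1)
  g <- g0 / sqrt(2); h <- h0 / sqrt(2)
  n <- length(x)
  v <- x
  W <- vector("list", level)
  for (j in seq_len(level)) {
    step <- 2^(j - 1)
    wj <- numeric(n); vj <- numeric(n)
    for (t in seq_len(n)) {
      for (l in seq_len(L)) {
        src <- ((t - 1) - (l - 1) * step) %% n + 1
        wj[t] <- wj[t] + h[l] * v[src]
        vj[t] <- vj[t] + g[l] * v[src]
      }
    }
    W[[j]] <- wj
    v <- vj
  }
  list(W = W, V = v)
}

# Match detected events to ground truth by time (tolerance in seconds);
# returns indices into `detected` for each truth event, NA if unmatched.
matchEvents <- function(truth, detected, tolS = 5e-4) {
  vapply(truth$time_s, function(tt) {
    if (nrow(detected) == 0) return(NA_integer_)
    i <- which.min(abs(detected$time_s - tt))
    if (abs(detected$time_s[i] - tt) <= tolS) i else NA_integer_
  }, integer(1))
}

# Reduced-size preset run used by unit/property tests (full-size runs
# live in the acceptance tests).
smallPresetRun <- function(name, seed, nEvents = 100, durationS = 8) {
  sim <- presetSample(name, seed = seed, nEvents = nEvents,
                      durationS = durationS)
  res <- processTrace(sim$trace)
  list(sim = sim, res = res)
}

# Full-size preset pipeline runs shared between acceptance criteria
# (computed once per session).
.acceptCache <- new.env(parent = emptyenv())
acceptancePresetRuns <- function() {
  if (!is.null(.acceptCache$runs)) return(.acceptCache$runs)
  runs <- lapply(c(pure_beads = "pure_beads", pure_cells = "pure_cells",
                   mixture = "mixture"), function(p) {
    sim <- presetSample(p, seed = 1)
    res <- processTrace(sim$trace)
    list(sim = sim, res = res)
  })
  .acceptCache$runs <- runs
  runs
}
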