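test_that("population amplitude draws follow the configured distribution", {
  spec <- populationSpec("bead", 1, 2, 0.05)
  expect_length(samplePopulation(spec, 0, seed = 1), 0)
  fixed <- populationSpec("bead", 1, 2, 0)
  expect_equal(samplePopulation(fixed, 25, seed = 1), rep(2, 25))
  amps <- samplePopulation(spec, 10000, seed = 7)
  expect_true(all(amps > 0))
  se <- 0.05 * 2 / sqrt(10000)
  expect_lt(abs(mean(amps) - 2), 3 * se)
  # reproducible under fixed seed
  expect_identical(amps, samplePopulation(spec, 10000, seed = 7))
  expect_error(populationSpec("bead", 1, -2, 0.1), "ampMeanUv")
  expect_error(populationSpec("bead", 1, 2, 1.2), "ampCv")
  expect_error(populationSpec("widget", 1, 2, 0.1), "kind")
})

test_that("cross-frequency scaling follows the circuit model", {
  grid <- defaultFrequencyGrid()
  flat <- scaleAcrossFrequencies(3, beadParticle(), frequencies = grid)
  expect_true(all(abs(flat - 3) < 1e-9))
  cellAmps <- scaleAcrossFrequencies(15, cellParticle(), frequencies = grid)
  expect_lt(cellAmps[5], cellAmps[2])  # 20 MHz below 500 kHz
  # exact per-channel values from the oracle ratios
  dz <- sapply(grid, function(f)
    Mod(oracleImpedance(1e-9, 1e4, 800, 100e-12, 400, f) -
        oracleImpedance(1e-9, 1e4, NULL, NA, NA, f)))
  expect_equal(unname(cellAmps), 15 * dz / dz[2], tolerance = 1e-12)
  expect_error(
    scaleAcrossFrequencies(1, beadParticle(), frequencies = c(1e6, 2e6)),
    "not present")
})

test_that("trace generation is deterministic with exact ground truth", {
  cfg <- traceConfig(nEvents = 40, durationS = 4, seed = 11)
  pops <- presetPopulations("pure_beads")
  a <- generateTrace(cfg, pops)
  b <- generateTrace(cfg, pops)
  expect_identical(traceChannels(a$trace), traceChannels(b$trace))
  expect_identical(a$events, b$events)
  expect_equal(nrow(a$events), 40)
  expect_true(!is.unsorted(a$events$time_s))

  # silence: no events, no noise, no drift
  quiet <- traceConfig(nEvents = 0, durationS = 1, noiseSigmaUv = 0,
                       driftAmplitudeUv = 0, seed = 1)
  z <- generateTrace(quiet, pops)
  expect_true(all(traceChannels(z$trace) == 0))
  expect_equal(nrow(z$events), 0)
})

test_that("noiseless pulses reproduce logged amplitudes on all channels", {
  cfg <- traceConfig(nEvents = 25, durationS = 4, noiseSigmaUv = 0,
                     driftAmplitudeUv = 0, seed = 3)
  out <- generateTrace(cfg, presetPopulations("mixture"))
  ch <- traceChannels(out$trace)
  t <- traceTimes(out$trace)
  fs <- samplingRate(out$trace)
  ampCols <- grep("^amp_uv_", names(out$events))
  for (e in seq_len(nrow(out$events))) {
    i0 <- round(out$events$time_s[e] * fs) + 1
    win <- (i0 - 20):(i0 + 20)
    for (k in seq_len(ncol(ch))) {
      # amplitude fidelity: pulse maximum equals the log
      expect_equal(max(ch[win, k]),
                   out$events[e, ampCols[k]], tolerance = 1e-6)
      # cross-channel coherence: same peak index in every channel
      expect_equal(which.max(ch[win, k]), 21L)
    }
  }
})

test_that("event placement rejects configurations that cannot fit", {
  cfg <- traceConfig(nEvents = 65, durationS = 0.2, seed = 1)
  expect_error(generateTrace(cfg, presetPopulations("pure_cells")),
               "overlap")
  expect_error(traceConfig(nEvents = 300, durationS = 0.2),
               "fit")
  expect_error(traceConfig(samplingRateHz = 1000, pulseWidthS = 1e-3),
               "sampling rate")
})

test_that("presets encode the three experimental samples", {
  cells <- presetSample("pure_cells", seed = 5, nEvents = 60,
                        durationS = 5)
  expect_true(all(cells$events$kind == "cell"))
  mix <- presetSample("mixture", seed = 5, nEvents = 200)
  expect_equal(nrow(mix$events), 200)
  tb <- table(mix$events$kind)
  expect_gt(tb[["bead"]], nrow(mix$events) / 2)  # beads dominate
  expect_true(tb[["aggregate"]] > 0)
  expect_error(presetSample("plasma"), "arg")
  # weights must sum to one
  bad <- list(populationSpec("bead", 0.5, 2, 0.05))
  expect_error(generateTrace(traceConfig(nEvents = 5, durationS = 1), bad),
               "sum to 1")
})
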