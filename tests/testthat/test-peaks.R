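test_that("nothing is detected on a flat noise-free trace", {
  t <- seq(0, 1, by = 1 / 4e4)
  flat <- MultiFrequencyTrace(t, matrix(0, length(t), 5),
                              defaultFrequencyGrid())
  ev <- detectPeaks(flat, rep(0, 5))
  expect_equal(nrow(ev), 0)
  expect_true(all(c("time_s", "amp_uv_500000", "snr_500000") %in%
                  names(ev)))
})

test_that("strong pulses are recovered at the right times and heights", {
  # 10 pulses at 20 sigma (6 uV over 0.3 uV noise), known times
  cfg <- traceConfig(nEvents = 10, durationS = 4, seed = 31)
  pops <- list(populationSpec("bead", 1, 6, 0))
  sim <- generateTrace(cfg, pops)
  res <- processTrace(sim$trace)
  expect_equal(nrow(res$events), 10)
  m <- matchEvents(sim$events, res$events, tolS = 2 / 4e4)
  expect_true(all(!is.na(m)))
  rec <- referenceAmplitudes(res$events)[m]
  expect_true(all(abs(rec - 6) / 6 < 0.05))
})

test_that("detection is scale-invariant and amplitudes scale linearly", {
  cfg <- traceConfig(nEvents = 15, durationS = 3, seed = 17)
  sim <- generateTrace(cfg, presetPopulations("pure_cells"))
  base <- processTrace(sim$trace)
  scaled <- MultiFrequencyTrace(traceTimes(sim$trace),
                                traceChannels(sim$trace) * 3.7,
                                traceFrequencies(sim$trace))
  up <- processTrace(scaled)
  expect_equal(nrow(up$events), nrow(base$events))
  expect_equal(up$events$time_s, base$events$time_s)
  expect_equal(referenceAmplitudes(up$events),
               3.7 * referenceAmplitudes(base$events), tolerance = 1e-6)
})

test_that("detrending is a no-op for detection on drift-free traces", {
  cfg <- traceConfig(nEvents = 20, durationS = 3, driftAmplitudeUv = 0,
                     seed = 23)
  sim <- generateTrace(cfg, presetPopulations("pure_cells"))
  full <- processTrace(sim$trace)
  # drift-free data: scanning the raw trace directly is a valid detector
  sigmas <- apply(traceChannels(sim$trace), 2, estimateNoiseSigma)
  direct <- detectPeaks(sim$trace, sigmas)
  expect_equal(nrow(full$events), nrow(direct))
  expect_equal(full$events$time_s, direct$time_s, tolerance = 1e-4)
  expect_equal(referenceAmplitudes(full$events),
               referenceAmplitudes(direct), tolerance = 0.05)
})

test_that("every detected event carries amplitudes and SNR for all channels", {
  run <- smallPresetRun("mixture", seed = 4, nEvents = 40, durationS = 4)
  ev <- run$res$events
  freqs <- defaultFrequencyGrid()
  for (f in freqs) {
    acol <- paste0("amp_uv_", format(f, scientific = FALSE))
    scol <- paste0("snr_", format(f, scientific = FALSE))
    expect_true(all(is.finite(ev[[acol]])))
    expect_true(all(is.finite(ev[[scol]])))
    expect_equal(ev[[scol]],
                 ev[[acol]] / run$res$noiseSigma[which(freqs == f)],
                 tolerance = 1e-9)
  }
  expect_error(detectPeaks(run$res$filtered, run$res$noiseSigma,
                           referenceFrequencyHz = 7e5), "not present")
})

test_that("detection is complete and unbiased on preset populations", {
  # reduced-size presets (100 events / 8 s), 10 fixed seeds
  relerr <- c()
  for (seed in 1:10) {
    for (p in c("pure_beads", "pure_cells", "mixture")) {
      run <- smallPresetRun(p, seed = seed)
      expect_equal(nrow(run$res$events), nrow(run$sim$events),
                   info = sprintf("%s seed %d", p, seed))
      m <- matchEvents(run$sim$events, run$res$events)
      expect_true(all(!is.na(m)),
                  info = sprintf("%s seed %d times", p, seed))
      if (p == "pure_beads")
        relerr <- c(relerr,
                    referenceAmplitudes(run$res$events)[m] /
                    referenceAmplitudes(run$sim$events) - 1)
    }
  }
  # amplitude unbiasedness: mean relative error below 5 percent
  expect_lt(abs(mean(relerr)), 0.05)
})
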