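test_that("mixture fitting recovers known component parameters", {
  # degenerate: identical amplitudes collapse to one zero-width component
  fit0 <- fitAmplitudeMixture(rep(2, 50), 2)
  expect_equal(fit0@nComponents, 1L)
  expect_equal(mixtureComponents(fit0)$sd_uv, 0)

  set.seed(14)
  amps <- c(rnorm(300, 2, 0.4), rnorm(300, 15, 3))
  fit <- fitAmplitudeMixture(amps, 2)
  comp <- mixtureComponents(fit)
  expect_equal(nrow(comp), 2)
  expect_true(!is.unsorted(comp$mean_uv))
  expect_lt(abs(comp$mean_uv[1] - 2) / 2, 0.10)
  expect_lt(abs(comp$mean_uv[2] - 15) / 15, 0.10)
  expect_equal(sum(comp$weight), 1, tolerance = 1e-6)

  expect_error(fitAmplitudeMixture(rnorm(5), 1), "at least 10")
  expect_error(fitAmplitudeMixture(amps, 5), "1, 2 or 3")
})

test_that("BIC model selection distinguishes unimodal from bimodal", {
  set.seed(15)
  bimodal <- c(rnorm(200, 2, 0.3), rnorm(100, 10, 1))
  selB <- selectMixtureComponents(bimodal, 1:2)
  expect_equal(selB$best, 2)
  expect_lt(selB$bic[["2"]], selB$bic[["1"]])
  unimodal <- rnorm(300, 5, 1)
  selU <- selectMixtureComponents(unimodal, 1:2)
  expect_equal(selU$best, 1)
})

test_that("gates capture the sample mean and covariance geometry", {
  ev <- data.frame(time_s = 1:3 / 10,
                   amp_uv_500000 = c(1, 2, 3), amp_uv_20000000 = 1:3,
                   snr_500000 = c(2, 8, 3), snr_20000000 = c(1, 2, 6))
  g <- buildGate(ev, scale = 10, name = "tiny")
  expect_true(all(inGate(g, ev)))  # scale large enough holds all points
  expect_equal(g@center, c(mean(ev$snr_500000), mean(ev$snr_20000000)))

  # isotropic cluster: ellipse axes equal within sampling error
  set.seed(16)
  iso <- data.frame(time_s = seq_len(2000) / 1000,
                    amp_uv_500000 = rnorm(2000, 10),
                    amp_uv_20000000 = rnorm(2000, 10),
                    snr_500000 = rnorm(2000, 20, 2),
                    snr_20000000 = rnorm(2000, 20, 2))
  gi <- buildGate(iso)
  ev_ratio <- eigen(gi@covariance)$values
  expect_lt(ev_ratio[1] / ev_ratio[2], 1.3)

  expect_error(buildGate(ev[1:2, ]), "at least 3")
  degenerate <- ev
  degenerate$snr_20000000 <- degenerate$snr_500000  # collinear
  expect_error(buildGate(degenerate), "singular|more events")
})

test_that("event classification partitions events deterministically", {
  mkEvents <- function(low, high) {
    data.frame(time_s = seq_along(low) / 100,
               amp_uv_500000 = low, amp_uv_20000000 = high,
               snr_500000 = low, snr_20000000 = high)
  }
  set.seed(18)
  beadCal <- mkEvents(rnorm(100, 7, 1), rnorm(100, 7, 1))
  aggCal <- mkEvents(rnorm(100, 80, 8), rnorm(100, 30, 4))
  beadGate <- buildGate(beadCal, name = "bead")
  aggGate <- buildGate(aggCal, name = "aggregate")

  # empty input: zero counts, no labels
  none <- classifyEvents(mkEvents(numeric(0), numeric(0)),
                         beadGate, aggGate)
  expect_equal(unname(none$counts), c(0L, 0L))

  # the gate centre is labelled with its own gate
  centre <- mkEvents(beadGate@center[1], beadGate@center[2])
  expect_equal(classifyEvents(centre, beadGate, aggGate)$events$label,
               "bead")

  # partition: every event gets exactly one label; counts sum to total
  probe <- mkEvents(runif(200, 0, 100), runif(200, 0, 40))
  cls <- classifyEvents(probe, beadGate, aggGate)
  expect_equal(sum(cls$counts), 200)
  expect_true(all(cls$events$label %in% c("bead", "aggregate")))

  # gate monotonicity: enlarging scale never shrinks membership
  for (s in c(0.5, 1, 2, 4)) {
    small <- buildGate(beadCal, scale = s)
    big <- buildGate(beadCal, scale = s * 2)
    expect_true(all(!inGate(small, probe) | inGate(big, probe)))
  }
  expect_error(classifyEvents(probe, beadGate), "aggregate")
})

test_that("threshold classification applies the 10 uV aggregate rule", {
  ev <- data.frame(time_s = 1:4, amp_uv_500000 = c(2, 9.9, 10.1, 25),
                   snr_500000 = c(2, 9.9, 10.1, 25) / 0.3)
  out <- thresholdClassify(ev, 10)
  expect_equal(out$events$label,
               c("bead", "bead", "aggregate", "aggregate"))
  expect_equal(unname(out$counts), c(2L, 2L))
  all_agg <- thresholdClassify(ev, 0)
  expect_true(all(all_agg$events$label == "aggregate"))
  empty <- thresholdClassify(ev[0, ], 10)
  expect_equal(unname(empty$counts), c(0L, 0L))
})

test_that("the Welch comparison behaves as a calibrated two-sample test", {
  x <- c(1.2, 1.9, 2.4, 2.2, 1.7)
  same <- comparePopulations(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(comparePopulations(1, c(1, 2)), "at least 2")

  # type-I error calibration at alpha = 0.05
  set.seed(19)
  rejections <- mean(replicate(1000, {
    comparePopulations(rnorm(30, 5), rnorm(30, 5))$p.value < 0.05
  }))
  expect_gt(rejections, 0.03)
  expect_lt(rejections, 0.07)
})

test_that("bead and cell SNR clusters separate in gate space", {
  beads <- smallPresetRun("pure_beads", seed = 6, nEvents = 80,
                          durationS = 6)
  cells <- smallPresetRun("pure_cells", seed = 6, nEvents = 80,
                          durationS = 6)
  bg <- buildGate(beads$res$events, name = "bead")
  cg <- buildGate(cells$res$events, name = "cell")
  # cells sit higher on both SNR axes than beads
  expect_true(all(cg@center > bg@center))
  # 1-SD ellipses do not claim each other's events
  expect_false(any(inGate(bg, cells$res$events)))
  expect_false(any(inGate(cg, beads$res$events)))
})
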