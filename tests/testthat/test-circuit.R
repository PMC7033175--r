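test_that("baseline impedance matches the closed form and its limits", {
  circ <- ElectrodeCircuit(C_dl_farads = 1e-9, R_s_ohms = 1e4)
  z <- baselineImpedance(circ, 5e5)
  # hand-evaluated: 2/(j*2*pi*5e5*1e-9) + 1e4
  expect_equal(Re(z), 1e4, tolerance = 1e-12)
  expect_equal(Im(z), -636.6197723675813, tolerance = 1e-12)
  # capacitors short at very high frequency: |Z| -> R_s
  expect_equal(Mod(baselineImpedance(circ, 1e15)), 1e4, tolerance = 1e-6)
  # degenerate huge capacitance: Z -> R_s at any frequency
  big <- ElectrodeCircuit(C_dl_farads = 1e3, R_s_ohms = 1e4)
  expect_lt(Mod(baselineImpedance(big, 1234) - 1e4) / 1e4, 1e-9)
  # magnitude strictly decreasing in f
  f <- c(1e5, 3e5, 1e6, 5e6, 2e7)
  expect_true(all(diff(Mod(baselineImpedance(circ, f))) < 0))
  expect_error(baselineImpedance(circ, 0), "positive")
  expect_error(ElectrodeCircuit(C_dl_farads = -1), "Cdl")
})

test_that("total impedance reproduces the two-electrode network exactly", {
  circ <- ElectrodeCircuit()
  cell <- cellParticle()
  # zero occlusion resistance: particle invisible at every frequency
  ghost <- cellParticle(deltaR = 0)
  for (f in defaultFrequencyGrid())
    expect_equal(totalImpedance(circ, ghost, f),
                 baselineImpedance(circ, f), tolerance = 1e-12)
  # frozen value from the independent reciprocal-sum oracle
  z <- totalImpedance(circ, cell, 5e5)
  expect_equal(Re(z), 10781.70054956161, tolerance = 1e-10)
  expect_equal(Im(z), -733.70137213874, tolerance = 1e-10)
  # membrane shorts at very high frequency: branch -> dR || Rc
  zhi <- totalImpedance(circ, cell, 1e15) - baselineImpedance(circ, 1e15)
  expect_equal(Mod(zhi), 800 * 400 / 1200, tolerance = 1e-4)
})

test_that("implementation matches the independent oracle on random networks", {
  set.seed(42)
  for (i in 1:100) {
    Cdl <- 10^runif(1, -10, -8)
    Rs <- 10^runif(1, 3, 5)
    dR <- 10^runif(1, 1, 4)
    Cm <- 10^runif(1, -12, -9)
    Rc <- 10^runif(1, 2, 5)
    f <- 10^runif(1, 5, 7.3)
    circ <- ElectrodeCircuit(Cdl, Rs)
    p <- cellParticle(deltaR = dR, Cm = Cm, Rc = Rc)
    zo <- oracleImpedance(Cdl, Rs, dR, Cm, Rc, f)
    expect_equal(totalImpedance(circ, p, f), zo,
                 tolerance = 1e-12)
    b <- beadParticle(deltaR = dR)
    expect_equal(totalImpedance(circ, b, f),
                 oracleImpedance(Cdl, Rs, dR, NA, 1, f),
                 tolerance = 1e-12)
  }
})

test_that("impedance change is flat for beads and declines for cells", {
  circ <- ElectrodeCircuit()
  bead <- beadParticle()
  cell <- cellParticle()
  f <- c(1e5, defaultFrequencyGrid())
  dzb <- deltaImpedanceMagnitude(circ, bead, f)
  expect_lt(diff(range(dzb)) / mean(dzb), 1e-9)
  dzc <- deltaImpedanceMagnitude(circ, cell, defaultFrequencyGrid())
  expect_true(all(diff(dzc) <= 0))
  expect_lt(dzc[5], dzc[2])               # 20 MHz below 500 kHz
  expect_lt(dzc[5], dzc[3])               # strictly below 1 MHz
  # pointwise against the oracle
  dzo <- sapply(defaultFrequencyGrid(), function(fr)
    Mod(oracleImpedance(1e-9, 1e4, 800, 100e-12, 400, fr) -
        oracleImpedance(1e-9, 1e4, NULL, NA, NA, fr)))
  expect_equal(dzc, dzo, tolerance = 1e-12)
  # normalized curve drops well below 0.9 by 20 MHz (oracle: 0.35765)
  expect_equal(dzc[5] / dzc[1], 0.3576489611, tolerance = 1e-6)
  expect_lt(dzc[5] / dzc[1], 0.9)
})

test_that("occlusion resistance follows the volume law", {
  expect_identical(occlusionResistance(100, 1), 100)
  expect_equal(occlusionResistance(100, 2), 800)
  expect_equal(occlusionResistance(100, 3), 2700)
  for (k in c(0.5, 1.3, 2, 5)) # exact cube law
    expect_equal(occlusionResistance(37, k) / occlusionResistance(37, 1),
                 k^3, tolerance = 1e-14)
  expect_error(occlusionResistance(-1, 2), "positive")
  expect_error(occlusionResistance(100, 0), "positive")
})

test_that("frequency response curve preserves grid order and exports CSV", {
  circ <- ElectrodeCircuit()
  bead <- beadParticle()
  one <- frequencyResponseCurve(circ, bead, 5e5)
  expect_equal(nrow(one), 1)
  expect_equal(one$delta_z_ohms,
               deltaImpedanceMagnitude(circ, bead, 5e5))
  crv <- frequencyResponseCurve(circ, bead)
  expect_equal(crv$frequency_hz, defaultFrequencyGrid())
  expect_lt(max(crv$delta_z_ohms) / min(crv$delta_z_ohms), 1.01)
  expect_error(frequencyResponseCurve(circ, bead, numeric(0)),
               "at least one")
  path <- tempfile(fileext = ".csv")
  writeFrequencyResponseCsv(crv, path)
  back <- read.csv(path)
  expect_equal(back$delta_z_ohms, crv$delta_z_ohms, tolerance = 1e-9)
})

test_that("circuit configuration round-trips through YAML and JSON", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("C_dl_farads: 2.0e-9", "R_s_ohms: 15000",
               "frequencies_hz: [300000, 500000, 1.0e6]",
               "particles:",
               "  cell:", "    delta_R_ohms: 600", "    R_c_ohms: 500"),
             yml)
  cfg <- readCircuitConfig(yml)
  expect_equal(cfg$circuit@Cdl, 2e-9)
  expect_equal(cfg$circuit@Rs, 15000)
  expect_equal(cfg$frequencies, c(3e5, 5e5, 1e6))
  expect_equal(cfg$particles$cell@deltaR, 600)
  expect_equal(cfg$particles$cell@Rc, 500)
  expect_s4_class(cfg$particles$aggregate, "ParticleModel")

  jsn <- tempfile(fileext = ".json")
  writeLines('{"C_dl_farads": 1e-9, "R_s_ohms": 9000}', jsn)
  cfg2 <- readCircuitConfig(jsn)
  expect_equal(cfg2$circuit@Rs, 9000)
  expect_equal(cfg2$frequencies, defaultFrequencyGrid())
})

test_that("aggregate particles gain bead volumes on the cell branch", {
  agg <- aggregateParticle(nBeads = 2)
  cell <- cellParticle()
  bead <- beadParticle()
  volRatio <- 1 + 2 * (bead@radius / cell@radius)^3
  expect_equal(agg@deltaR, cell@deltaR * volRatio)
  expect_equal(agg@Cm, cell@Cm)
  expect_identical(agg@kind, "aggregate")
  # aggregates keep the cell's high-frequency decline
  circ <- ElectrodeCircuit()
  dz <- deltaImpedanceMagnitude(circ, agg, defaultFrequencyGrid())
  expect_true(all(diff(dz) <= 0))
})
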