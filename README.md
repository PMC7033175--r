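# impedCyto

Multi-frequency microfluidic impedance cytometry analysis for
immuno-magnetically separated samples: differentiate bare magnetic
beads, cells and bead–cell aggregates from their transit-pulse
amplitudes and frequency responses, and count the aggregates as the
readout of surface-marker expression.

## Who this is for

Impedance cytometry senses single particles transiting a micropore
between two electrodes: each transit produces a voltage pulse whose
height scales with particle volume. When antibody-coated magnetic beads
are used to capture marker-expressing cells, the magnet pulls down both
bare beads and bead–cell aggregates; this package implements the
electronic analysis that separates them. It is aimed at people building
or evaluating such assays who need a tested, reproducible reference
pipeline — including a synthetic-data generator with ground truth, since
raw lock-in traces for this kind of experiment are rarely deposited.

## The model and the method

The sensor with a particle in the pore is the lumped network

```
Z(f) = 2/(jωC_dl) + R_s + ΔR ∥ ( 2/(jωC_m) + R_c ),   ω = 2πf
```

with double-layer capacitance `C_dl`, solution resistance `R_s`,
occlusion resistance `ΔR` (proportional to particle volume — twice the
radius means 8× the low-frequency impedance change), membrane
capacitance `C_m` and cytoplasm resistance `R_c`. Beads have an open
membrane branch, so their impedance change `|ΔZ(f)|` is flat in
frequency; cells short their membrane above ~1 MHz and their `|ΔZ|`
falls — the basis of bead/cell discrimination.

The analysis chain is:

1. **simulate** (or load) multi-frequency lock-in traces
   (300 kHz–20 MHz, µV amplitudes) containing transit pulses, baseline
   drift and noise;
2. **process**: MODWT wavelet detrend + denoise, then matched-template
   peak detection at 5σ on the 500 kHz reference channel, reading
   per-frequency amplitude and SNR for every event;
3. **analyze**: Gaussian-mixture fits of the amplitude distributions,
   two-frequency (500 kHz, 20 MHz) SNR covariance-ellipse gates built
   from pure-bead and pure-cell calibration runs, aggregate counting by
   ellipse gating and by the simple >10 µV amplitude rule, and a Welch
   test of bead-vs-cell separability.

## Worked example

```r
library(impedCyto)

# simulate the three study samples and run the full chain
beads <- presetSample("pure_beads", seed = 1)   # 300 events, ~2/10 uV
cells <- presetSample("pure_cells", seed = 1)   # 300 events, ~15 uV
mix   <- presetSample("mixture",    seed = 1)   # 200 events, beads + aggregates

rb <- processTrace(beads$trace)
rc <- processTrace(cells$trace)
rm_ <- processTrace(mix$trace)
nrow(rb$events); nrow(rc$events); nrow(rm_$events)
#> [1] 300
#> [1] 300
#> [1] 200

# bimodal pure-bead amplitude distribution: singles vs doublets
mixtureComponents(fitAmplitudeMixture(referenceAmplitudes(rb$events), 2))
#>       weight  mean_uv     sd_uv
#> 1 0.91333333 1.990218 0.1265133
#> 2 0.08666667 9.745233 0.9347645

# gate in (SNR@500kHz, SNR@20MHz) space and count aggregates
bg <- buildGate(rb$events, name = "bead")
cg <- buildGate(rc$events, name = "cell")
out <- rm_$events[gateDistance(bg, rm_$events) > 3, ]
ag <- buildGate(out, name = "aggregate")
classifyEvents(rm_$events, bg, ag, cg)$counts
#>      bead aggregate      cell
#>       151        49         0
sum(mix$events$kind == "aggregate")   # ground truth
#> [1] 49

thresholdClassify(rm_$events, 10)$counts   # the 1-D >10 uV rule
#>      bead aggregate
#>       153        47

comparePopulations(referenceAmplitudes(rb$events),
                   referenceAmplitudes(rc$events))$p.value
#> [1] 1.49023e-237
```

The mixture sample is dominated by bare beads (as in a real capture
experiment, where beads are supplied in excess); the 49 events the
ellipse gate assigns to the aggregate class match the injected ground
truth exactly, and the threshold rule comes within two events (it misses
aggregates drawn below 10 µV).

`cmdSimulate()` / `cmdProcess()` / `cmdAnalyze()` run the same stages
against files with a JSON run manifest, `runPresetPipeline()` drives all
of them, and `inst/scripts/impedcyto.R` exposes them as shell
subcommands.

## Documentation

The methods vignette (`vignettes/impedance-cytometry.Rmd`) documents the
circuit model and its parameter defaults, what the synthetic generator
does and does not emulate, every numerical choice in the signal chain
(wavelet depth, selective thresholding, matched-template quantification,
σ conventions), the gating rules and tie-breaks, and known limitations.
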