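# MARedge

Automatic, gray-value-independent quantification of metal artifact
reduction (MAR) in cone-beam CT (CBCT) image stacks, by edge counting.

Dense dental prostheses cast streak artifacts — alternating bright and
dark bands — across axial CBCT slices. Vendors ship MAR reconstruction
options, but CBCT gray values are too unstable across machines and
settings for ROI-based quantification. `MARedge` instead detects edges in
every slice with a Canny detector extended by an impulse-noise-removal
stage, counts each **edge** as one 8-connected component of edge pixels
("a continuous line with no breaks"), and compares paired acquisitions of
the same object taken with MAR off and on through the **edge reduction
ratio**

```
reduction (%) = (E_off − E_on) / E_off × 100
```

on stack totals, with per-slice count differences feeding the statistical
layer: Shapiro–Wilk normality screening, Welch's one-way ANOVA with the
Games–Howell post hoc across prosthesis types, and Welch t-tests across
scan modes (voxel size × tube voltage). Because the study-grade raw scans
behind this design are not redistributable, the package also ships a
synthetic arch-phantom simulator that emits matched MAR-off/MAR-on stacks
with *exact* ground truth (MAR modeled as streak-subset removal), used for
end-to-end validation.

For whom: imaging scientists and medical physicists evaluating MAR
implementations or exposure protocols, and anyone needing a reproducible,
scriptable edge-count pipeline over axial slice stacks.

## Worked example

Simulate a phantom pair with 10 streaks in the MAR-off stack and the same
geometry minus 6 streaks in the MAR-on stack, then measure:

```r
library(MARedge)

sim <- makePair(phantomSpec(), kOff = 10, kOn = 4, seed = 42)
sim
#> SimulatedPair: 10 off-streaks vs 4 on-streaks per slice, true reduction 60.0% (seed 42)

rep <- analyzePair(sim, phantomEdgeParams())
rep
#> ReductionReport: 10 slices | edges off 120, on 60 | reduction 50.00% | per-slice diff 6.00 +/- 0.00
```

Each noise-free slice counts 12 components with MAR off (10 streak bands +
arch contour + insert contour) and 6 with MAR on, so the measured ratio is
50% against the combinatorial truth of 60% — the two shared anatomy
contours produce a structural, seed-independent offset that vanishes as
streaks outnumber anatomy. Group-level statistics follow the same
interfaces:

```r
welchAnova(list(
  gold     = c(72.1, 68.4, 75.0, 70.2, 66.9),
  pfm      = c(31.2, 35.8, 29.4, 33.1, 30.7),
  zirconia = c(22.5, 25.1, 21.8, 24.4, 23.0)))
#>          F df1      df2      p.value
#> 1 426.7575   2 7.062085 4.312717e-08
```

Real data enter through `readStack()` (PNG/TIFF/BMP slice directories or
uncompressed DICOM series), `trimBlankSlices()`, `pairStacks()` and the
same `analyzePair()`; reports serialize losslessly to CSV/JSON with
`writeReport()`/`readReport()`.

## Command line

A thin wrapper over the same functions lives in `exec/maredge`:

```sh
maredge simulate --spec phantom.spec --out sim/
maredge count    --stack sim/off --out counts.csv [--save-edges edges/]
maredge compare  --off sim/off --on sim/on --out report.csv
maredge stats    --reports gold=g.csv,pfm=p.csv --out stats.csv
```

Configuration is a flat `key = value` file (see `readRunConfig()`); every
failure exits nonzero with a one-line diagnostic.

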