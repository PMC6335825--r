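# phagostate

Quantification of the phagocytic state of brain myeloid cells (microglia,
macrophages) from dual-channel fluorescence images: a membrane-marker
channel (e.g. CD11b) that defines the cell outline and a target channel
carrying lysosomal signal (e.g. CD68) or phagocytosed fluorescent beads.

As phagocytosis progresses, lysosomes redistribute: during active target
internalization they cluster against the plasma membrane; during terminal
digestion/autophagy they disperse into the cytoplasm. `phagostate` turns
this redistribution into per-cell numbers:

* **GLCM texture** of the target signal inside the traced outline, from
  the gray-level co-occurrence matrix p(i,j) at step size 1 px, direction
  0°:
  - angular second moment `ASM = Σ p(i,j)²`
  - inverse difference moment `IDM = Σ p(i,j)/(1+(i−j)²)`
  - `entropy = −Σ p(i,j) ln p(i,j)`

  Clustered (homogeneous) signal → high ASM/IDM, low entropy.
* **Membrane-distance shells**: inward Euclidean distance bands at
  100/300/500/700 nm from the traced membrane and the fraction of
  integrated density per band — the within-700 nm fraction quantifies
  membrane-proximal lysosome positioning.
* **Shape descriptors**: circularity `4πA/P²` and solidity
  `A/A_hull`, controls for morphology-driven texture differences.
* **Bead uptake**: threshold segmentation, 8-connected counting by the
  centroid rule in the cytoplasm and in the 700 nm band, and time-lapse
  uptake curves.
* **A ground-truthed simulator** (`generateCell`, `generateTimelapse`)
  that renders dual-channel cells with known spot positions, membrane
  distances and uptake counts, so every stage is testable without
  microscope data. Spots are placed by a mixture: a fraction φ
  membrane-proximal (≤ 700 nm), the rest uniform over the interior.

Audience: quantitative microscopists and neuroimmunology labs analyzing
superresolved (or high-NA confocal) images of phagocytic cells, and anyone
needing a validated GLCM/shell-analysis reference implementation in R.

## Worked example

Simulate one membrane-clustered cell and analyze it end-to-end:

```r
library(phagostate)

spec <- cellSpec(imageSize = 512, nSpots = 80,
                 clusteringFraction = 0.8, seed = 7)
sim <- generateCell(spec)       # $images, $truth, $roi
rec <- analyzeCell(sim$images, sim$roi, cellId = "demo",
                   group = "clustered")
round(t(rec[, c("asm", "idm", "entropy", "frac_within_700",
                "circularity", "solidity",
                "n_beads_total", "n_beads_band")]), 4)
#>                    [,1]
#> asm              0.7525
#> idm              0.8905
#> entropy          1.2769
#> frac_within_700  0.7829
#> circularity      0.8128
#> solidity         0.9384
#> n_beads_total   65.0000
#> n_beads_band    53.0000
```

With φ = 0.8, 78 % of the integrated lysosomal density lies within 700 nm
of the membrane and 53 of the 65 counted spots sit in the 700 nm band —
the signature of active internalization. The ground truth agrees:

```r
fractionWithinBoundary(data.frame(x = sim$truth$x_px,
                                  y = sim$truth$y_px), sim$roi)
#> [1] 0.8375
```

(80 % planted proximal plus the uniform spots that happen to fall in the
band.) A spread cell (`clusteringFraction = 0`) gives a within-700 nm
fraction near the band's area fraction (~0.11 at these conditions) and a
higher entropy.

Whole studies — simulated cohorts, time-lapse runs, or images on disk —
run through `runExperiment()` (see `?runExperiment`), which writes
`cells.csv`, `comparisons.csv` (Welch t tests and the two-way group × band
ANOVA with Šidák post hoc) and a run log with every resolved parameter and
seed. A thin CLI wrapper lives in `exec/phagostate`
(`phagostate simulate|analyze|compare|run --config cfg.yaml`).

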