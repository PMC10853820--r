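# centrofish

Quantifying where an mRNA and its encoded protein sit relative to the
mitotic centrosome, from single-molecule RNA FISH (smFISH) microscopy.

## The problem

In mitotic human cells some transcripts are localized co-translationally:
ASPM mRNA forms a ring around each spindle-pole centrosome, biased toward
the **astral** face, while ASPM protein concentrates on the opposite
**spindle** face — and after a puromycin pulse-washout the RNA takes hours
to return to the centrosome, far longer than the ~10 minutes needed to
translate its 3477-codon ORF at 6 amino acids per second. Turning such
images into numbers requires a small set of careful measurements, which
this package implements for anyone doing pericentrosomal localization
quantification:

* **Disk-ROI enrichment** — total intensity in a circle (default radius
  2 µm) around the centrosome minus a matched in-cell background
  (median of 10 seeded placements that avoid the centrosomes):
  `enrichment = disk_total − background_total`.
* **Signed line-profile peak position** — each channel is sampled along
  the spindle→astral axis through the peak centrosome-marker signal
  (±1 µm, 0.05 µm steps, bilinear); the statistic is the signed argmax
  position, negative = spindle side, positive = astral side.
* **Washout recovery onset** — per-timepoint two-sided Welch t-tests of
  enrichment against the 0-hour group; the onset is the earliest
  timepoint that is both significant (α = 0.05) and elevated.
* **Detection** — centrosome localization (smoothed local maxima +
  subpixel centroid) and Laplacian-of-Gaussian smFISH spot detection with
  a median + k·MAD threshold.
* **A ground-truthed synthetic scene generator** — metaphase cells with
  two centrosomes, a von Mises astral-biased RNA ring (concentration κ),
  a protein blob displaced along the spindle axis, Poisson shot noise and
  Gaussian read noise — so every estimator is validated against known
  truth, and no external data are needed.
* **smiFISH probe design** — all 26–32-nt windows with 40–60% GC, greedy
  non-overlapping tiling up to 48 probes, the shared secondary-hybridization
  overhang appended to every oligo, and the 20% molar-excess secondary mix
  arithmetic.

Everything takes and returns tidy data frames; results pipe straight into
dplyr and ggplot2 (`autoplot()`, `tidy()`, `glance()` are provided).

## Worked example

```r
library(centrofish)

sim   <- simulate_cell(scene_config(), seed = 2)   # one metaphase cell
quant <- quantify_scene(sim$scene, seed = 3)
quant[, c("centrosome_id", "channel", "enrichment", "peak_position_um")]
#>   centrosome_id channel enrichment peak_position_um
#> 1             1 marker       8134.             0
#> 2             1 rna          3779.             0.45
#> 3             1 protein      9032.            -0.45
#> 4             1 dna          -236.             0.7
#> 5             2 marker       8464.             0
#> 6             2 rna          3476.             0.5
#> 7             2 protein      9294.            -0.3
#> 8             2 dna           199.            -0.1
```

The marker peaks at 0 by construction; the RNA peak sits on the astral
side (+0.45, +0.50 µm — the biased ring), the protein on the spindle side
(−0.45, −0.30 µm), and DNA shows no centrosomal enrichment. A full
washout time-course:

```r
sims  <- simulate_timecourse(scene_config(), washout_kinetics(),
                             n_cells_per_timepoint = 10, seed = 7)
quant <- quantify_timecourse(sims, channels = "rna",
                             profile_channels = NULL, seed = 7)
recovery_onset(quant, channel = "rna", alpha = 0.05)
#> <recovery_result> channel 'rna', alpha 0.05 (none)
#>   onset: 3 h
#>   timepoint  mean    sd     n statistic  p_value significant
#>       0      358.  717.    20     NA     NA       FALSE
#>       0.167  388.  640.    20     0.137  8.9e- 1  FALSE
#>       0.75   137.  643.    20    -1.03   3.1e- 1  FALSE
#>       1      607.  824.    20     1.02   3.2e- 1  FALSE
#>       2      515.  795.    20     0.656  5.2e- 1  FALSE
#>       3     1261.  466.    20     4.72   4.3e- 5  TRUE
#>       4     2549.  618.    20    10.4    1.7e-12  TRUE
```

Centrosomal RNA enrichment is flat through 2 h, first significantly
elevated at **3 h**, and still rising (but below the untreated baseline)
at 4 h — the relocalization-lag readout. And the translation clock:

```r
translation_time(aspm_orf_codons)
#>   minutes minutes_rounded
#> 1    9.66              10
```

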