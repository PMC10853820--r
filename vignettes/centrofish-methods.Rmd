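---
title: "Quantifying pericentrosomal RNA and protein localization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pericentrosomal RNA and protein localization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Some mRNAs are localized co-translationally: the transcript travels to the
subcellular site where its protein acts, and nascent-peptide signals help
anchor it. A striking case is ASPM in mitotic human cells: smFISH shows the
RNA forming a ring around each spindle-pole centrosome, biased toward the
*astral* face (the side toward the cell cortex), while immunofluorescence
places the ASPM protein on the opposite, *spindle* face. After a pulse of
translation inhibition (puromycin) and washout, the RNA only re-accumulates
at mitotic centrosomes hours later, and incompletely — far slower than the
~10 minutes it takes to translate the 3477-codon ORF at a standard 6
amino acids per second.

`centrofish` implements the quantitative layer of such a study:

1. a ground-truthed **synthetic microscopy-scene generator** for metaphase
   cells (so every estimator can be validated against known truth);
2. **detection**: centrosome localization, signed spindle→astral frames,
   and Laplacian-of-Gaussian smFISH spot detection;
3. **quantification**: disk-ROI enrichment with in-cell background
   subtraction, and the signed line-profile peak-position statistic;
4. **statistics**: Welch t-tests, power-based sample sizing, washout
   recovery-onset detection, and the ORF translation-time estimate;
5. **smiFISH probe design** under the published length/GC rules.

All user-facing functions take and return tidy tables, so results flow
directly into dplyr/ggplot2.

## The synthetic scene model

A scene is one metaphase cell in a 2-D image (the analogue of a
maximum-intensity projection, which is also the convention the analysis
assumes). Geometry, per channel:

* **marker** (pericentrin-like): two diffraction-limited blobs at the
  spindle poles, separated by `centrosome_separation` along the x axis.
  Each centrosome's *astral* unit vector points away from the
  inter-centrosome midpoint; the signed axis coordinate is negative on the
  spindle side.
* **rna**: `n_rna_centrosomal` spots per centrosome on a ring of radius
  `rna_ring_radius`, with angular positions drawn from a von Mises law
  centred on the astral direction with concentration $\kappa$
  (`rna_astral_bias`; $\kappa = 0$ is an unbiased ring), plus
  `n_rna_free` spots uniform in the cell disk. Spots are isotropic
  Gaussians of width `psf_sigma`.
* **protein**: a Gaussian blob of width `protein_sigma` displaced by the
  signed `protein_offset` along each centrosome's axis (negative =
  spindle side).
* **dna**: a metaphase plate (narrow along the spindle axis, wide across
  it) or a round blob for non-metaphase `stage_label`s. The stage label is
  annotation carried into the ground truth; no classifier is involved.

Photometrically every pixel is
$\max\{0,\ \mathrm{Poisson}(S + b) + \mathcal{N}(0, \sigma_r)\}$
with $S$ the summed Gaussian signal, $b$ = `background_level` and
$\sigma_r$ = `read_noise_sd`. With the default amplitudes (RNA peak 50
photons over background 100, read noise 2) a single RNA spot sits at
SNR $\approx 5$, a realistic regime for widefield smFISH. Identical
`(config, seed)` reproduces a scene bitwise.

Defaults: pixel size 0.1 µm (typical 60–100× sampling), PSF σ 0.12 µm,
cell radius 10 µm, pole separation 8 µm, 8 ring spots per centrosome
(the true pericentrosomal copy number is not established; this is a
plausible, tunable choice), 40 free spots, ring radius 0.5 µm,
$\kappa = 2$ and protein offset $-0.3$ µm (a clear but sub-resolution
asymmetry of the kind the line-profile statistic is designed to resolve).

What the simulator deliberately omits: spot brightness heterogeneity
(opt-in via `rna_amplitude_cv`; off by default so detection tests stay
sharp), 3-D optics and deconvolution artefacts, neighbouring cells,
autofluorescence gradients, and chromatic misregistration. Passing the
test suite therefore validates the estimators' correctness and their
behaviour under shot/read noise — not robustness to every real-world
artefact.

### Washout kinetics

Recovery of centrosomal RNA after inhibitor washout is modelled as a
piecewise-linear ramp: the per-centrosome count is
$\mathrm{round}(n \cdot r(t))$ with $r(t) = 0$ for $t \le \text{lag}$,
rising linearly to `recover_fraction` at `end_time`. The default fixation
grid is 0, 10, 45 min, 1, 2, 3, 4 h. Defaults `lag = 2 h`,
`recover_fraction = 0.6`, `end_time = 4 h` encode the observed phenotype:
nothing detectable through the 2-hour fixation, first centrosomal signal
at the 3-hour fixation, and only partial (60%) recovery at 4 h. Note the
boundary convention — the ramp starts *at* the lag, so a lag equal to a
grid point leaves that timepoint empty; first detectable signal appears at
the next fixation. A ramp (rather than a sigmoid) is the weakest
assumption consistent with a monotone, partial recovery.

## Detection

**Centrosomes** are local maxima of the Gaussian-smoothed marker channel
above `median + 5·MAD`, greedily thinned to a minimum mutual separation
(strongest first), then refined by an intensity-weighted centroid in a
3×3 window. On noise-free scenes both centres are recovered to < 0.5 px.

**Frames**: with exactly two centrosomes (the metaphase assumption — one
analysed cell per field; crowded fields are out of scope), each
centrosome's axis is the unit vector from its partner through itself.
This reproduces the ground-truth astral orientation by construction and
is verified against it across seeds.

**Spots** are detected on a scale-normalised, sign-flipped
Laplacian-of-Gaussian response at the PSF scale (zero-sum kernel, so flat
background contributes nothing; FFT convolution with circular boundary,
which makes detection commute exactly with integer circular shifts).
Strict local maxima above `median + k·MAD` of the response (default
`k = 5`) are kept and centroid-refined. At the default SNR the detector
reaches F1 ≥ 0.90 against ground truth with ≤ 1 false positive per blank
image; raising `k` can only remove detections.

## Quantification

**Disk enrichment** follows the subtraction rule: total intensity in a
circular ROI around the centrosome minus a matched in-cell background.
The ROI default is *radius* 2 µm — "2 µm around the centrosome" is
ambiguous between radius and diameter, so the radius reading was chosen
and the parameter left configurable. Membership is pixel-centre-in-circle
with no partial-pixel weighting (matching how FIJI-style ROI measurements
count pixels, and keeping a brute-force oracle exact); distances are
compared in pixel units with a 10⁻⁹ slack so exactly-on-boundary pixels
are treated identically for every grid-aligned placement — which is what
makes enrichment exactly zero on a uniform image. The background is the
median of the same disk sum over 10 seeded random placements inside the
cell mask, each ≥ 2× radius from every centrosome and fully inside the
image; placement is seeded, so results are reproducible, and a cell with
no valid placement after 1000 tries raises an error rather than returning
a biased background. Enrichment is `disk − background`, exactly, and may
legitimately be negative.

**Line profiles** re-centre on the marker peak first: the marker channel
is sampled along the axis on a fine grid (step/5) within ±0.5 µm and the
profile origin moved to its maximum, so position 0 means "peak PCNT
signal". All channels are then sampled by bilinear interpolation at
signed positions −L…+L (default L = 1 µm) in steps of 0.05 µm — sub-pixel,
since no sampling rule is prescribed by the measurement itself. The
**peak position** of a channel is the argmax over that grid, with ties
broken by smallest |position| and then toward the spindle (negative)
side; a constant profile therefore reports 0 rather than an arbitrary
end. The tie rule matters only for degenerate profiles but is stated and
tested so the statistic is a function, not a convention of the optimiser.

With defaults this machinery recovers true protein offsets of −0.4…−0.2
µm with mean absolute error ≤ 0.1 µm (one pixel) under full noise, and on
astral-biased scenes ($\kappa = 2$, offset −0.3 µm, 30 cells) yields mean
RNA peak positions > 0 and protein < 0 with a significant separation —
the quantitative signature of astral RNA vs spindle-side protein.

## Statistics

Group comparisons use the **two-sided Welch t-test** (`two_sample_t`).
"Student" tests with pooled variance were the plausible alternative;
Welch is the safer default under unequal variances and agrees with the
pooled test when variances match. Its type-I error is verified at
0.05 ± 0.01 over 10⁴ null simulations. `required_n` inverts the standard
two-sample power calculation (`power.t.test`) for a target power at a
given Cohen's d; conventional defaults α = 0.05, power = 0.8 are used
since the original power analysis inputs are not recorded.

**Recovery onset** (`recovery_onset`) tests each post-washout timepoint
against the 0-hour group and reports the earliest timepoint that is both
significant and *elevated* — the direction gate is explicit because
"relocalization" is one-directional while the test itself is two-sided.
By default no multiple-testing correction is applied across timepoints
(matching the original analysis, which reports none); `p_adjust = "holm"`
is available, and is worth using when the onset is scanned over many
timepoints: with six uncorrected comparisons at α = 0.05, the chance of
declaring some spuriously early onset is ≈ 10% even when the true onset
is detected perfectly. The replicate-level property test in this package
uses the Holm option for exactly that reason. When an untreated baseline
mean is supplied, the result also reports whether the final timepoint
remains below baseline (the "did not recover to baseline" readout).

`translation_time` is the back-of-envelope clock: codons / (aa·s⁻¹) / 60,
with a convenience rounding to the nearest 5 minutes; the packaged
`aspm_orf_codons = 3477` gives 9.66 → "about 10" minutes at 6 aa/s.

## Probe design

smiFISH primaries are unlabeled probe sequences carrying a shared 28-nt
overhang (`smifish_overhang`, GC 0.5) bound by a fluorophore-conjugated
secondary. `enumerate_candidates` lists *every* window of length 26–32 nt
with GC in [0.40, 0.60] (inclusive); `select_probes` then tiles the
transcript greedily left-to-right with a ≥ 2-nt gap, preferring at each
start the window with GC closest to 0.50 (ties: shorter, then earlier),
stopping at 48 probes — the published pool size. Thermodynamic (ΔG)
scoring of the Oligostan kind is deliberately *not* reimplemented; the
printed length/GC rules are the contract here, so sets designed by this
package are a superset-filter approximation, not Oligostan output.
Probes are reported in sense-strand coordinates; `hybridizing = TRUE`
emits reverse-complemented probe portions (the strand that actually
anneals) since the emitted strand is a bench-level convention.
`secondary_mix` applies the 20% molar excess to the primary pool
concentration (20 µM → 24 µM).

## Numerical and design choices, in brief

* Coordinates: (y, x) order, 0-based pixel indices, physical position =
  index × pixel size at pixel centres; all lengths in µm, intensities in
  photons.
* Images are stored as 16-bit multi-page TIFF with a JSON sidecar
  (pixel size, channel names, intensity scale, stage, timepoint, cell id);
  quantisation error is bounded by scale/65535. A bare TIFF without
  sidecar requires explicit pixel size and channel names.
* Seeding: every stochastic step (scene sampling, background-ROI
  placement) takes an explicit seed; `run_pipeline` re-derives per-image
  seeds deterministically, so identical configs give byte-identical
  outputs, and every output table carries the configuration hash.
* Degenerate inputs: uniform images yield no detections; a detected
  singleton centrosome is an error at frame building (named by cell);
  all-NA profile channels and invalid configurations fail with the field
  named.
* Problem sizes used by the tests and the acceptance analysis: 10 cells
  (20 centrosomes) per timepoint across the 7-point washout grid; 30
  cells per condition for the offset- and sign-recovery properties; 10⁴
  null draws for test calibration; 100 random 1-kb transcripts for the
  probe-enumeration equivalence. These are the scales at which the Monte
  Carlo bounds quoted above are tight enough to be meaningful.

## Known limitations

2-D only (a 3-D render is out of scope, as is deconvolution); one mitotic
cell per field; no per-spot colocalization statistics; no recovery-curve
fitting (the onset statistic is deliberately model-free); probe design
checks no specificity against a transcriptome. The synthetic generator is
a validation instrument — parameters are chosen to be realistic, but the
pericentrosomal RNA copy number in real metaphase cells is unknown, so
absolute enrichment values are not calibrated to any real microscope.

## A worked example

```{r example}
library(centrofish)
library(dplyr)

# one metaphase cell, astral-biased RNA, spindle-side protein
sim <- simulate_cell(scene_config(), seed = 1)
quant <- quantify_scene(sim$scene, seed = 1)
quant |> select(centrosome_id, channel, enrichment, peak_position_um)

# full washout experiment
sims  <- simulate_timecourse(scene_config(), washout_kinetics(),
                             n_cells_per_timepoint = 10, seed = 7)
quant <- quantify_timecourse(sims, channels = "rna",
                             profile_channels = NULL, seed = 7)
rec   <- recovery_onset(quant, channel = "rna", alpha = 0.05)
glance(rec)      # onset = 3 h with the default kinetics
autoplot(rec)

# probe pool for a transcript
probes <- design_probes(paste(sample(c("A","C","G","T"), 5000,
                                     replace = TRUE), collapse = ""))
nrow(probes)     # 48
```
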