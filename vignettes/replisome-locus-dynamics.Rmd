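---
title: "Quantifying replisome and chromosomal locus dynamics in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replisome and chromosomal locus dynamics in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package addresses

During chromosome replication in *E. coli*, either the replication machinery
(the replisome) could travel along a stationary chromosome, or chromosomal
loci could be brought to a spatially constrained replisome. Time-lapse
fluorescence microscopy of cells growing in a mother machine — a replisome
label in one color and a chromosomal locus label (a fluorescent
repressor–operator array) in another — lets the two hypotheses be separated
quantitatively. `replifoci` implements the analysis chain for this kind of
experiment:

1. projection of detected foci into a cell-internal coordinate system and
   cell-cycle-resolved 2D location histograms;
2. linking of per-frame foci into trajectories and detection of replication
   initiation as the start of a replisome trajectory;
3. initiation-aligned RMSD with removal of the net average movement,
   whose plateau discriminates particle movement within a region from
   cell-to-cell variability in the region's placement;
4. 1-second displacement statistics (from paired frames acquired 1 s apart)
   binned by cell area and by position inside the cell;
5. two-channel landmark registration and one-to-one replisome–locus pairing,
   giving distance-versus-cell-area profiles;
6. the exponential replication-size model connecting a locus's genomic
   position to the cell area at which it is replicated.

Because raw microscopy is outside the package's scope, a synthetic generator
produces mother-machine-like datasets with known ground truth; every
analysis stage is validated against it end to end.

## The replication-size model

Replication initiates at a cell area $A_\mathrm{init}$ and the two forks
proceed at constant speed for the C-period $C$. With cells growing
exponentially in area at rate $\mu = \ln 2 / T_d$, a locus at genomic
fraction $\alpha$ (distance from *oriC* divided by half the chromosome
length, so $\alpha = 0$ is the origin and $\alpha = 1$ the terminus) is
replicated when the cell reaches

$$A(\alpha) = A_\mathrm{init}\, e^{\mu C \alpha}.$$

Defaults are the intermediate-growth parameter set: $A_\mathrm{init} =
2.05\ \mu m^2$, $T_d = 50$ min, $C = 45$ min, giving $A(1) \approx
3.83\ \mu m^2$.

```{r}
library(replifoci)
p <- replication_params(A_init = 2.05, T_d = 50, C = 45)
predicted_replication_area(c(0, 0.5, 1), p)
```

## What the synthetic generator emulates

Each lineage is one mother-machine lane: the old pole is anchored at the
closed end, growth extends the cell along the channel, and at division the
old-pole daughter is followed while the sibling is discarded. The model
components, with defaults and the reasoning behind them:

* **Growth and division.** Exponential area growth, per-cycle rate noise
  (lognormal CV 0.05); division is a sizer at twice the mean birth area with
  lognormal noise (CV 0.1). Area maps to length through a constant width of
  1 µm (the channel width), $L = A / W$. Mean birth area is 1.85 µm², so
  initiation at 2.05 µm² falls a few minutes after birth, the
  initiation-to-division interval (≈ 43 min) holds both the C-period and the
  20-min RMSD window, and cells routinely reach $A(1)$ before dividing. A
  larger birth size would leave a substantial fraction of cells born already
  past the initiation threshold, censoring the initiation-size distribution
  upward. Note that the interval between successive initiations is one
  doubling time regardless of the division rule (area doubles between
  threshold crossings), so initiation detection is insensitive to this
  choice.
* **Initiation and replisomes.** A per-cycle initiation threshold (lognormal
  CV 0.03 about $A_\mathrm{init}$) spawns two replisome clusters at the
  ±L/4 long-axis points for one C-period. Confinement is a stationary
  mean-reverting (Ornstein–Uhlenbeck-type) fluctuation about the home point,
  simulated with the exact discrete update
  $x_{t+\Delta} = x_t e^{-\Delta/\tau} + \mathcal N\!\big(0,
  \sigma^2 (1 - e^{-2\Delta/\tau})\big)$, which is free of time-step bias at
  both the 1-min frame grid and the 1-s doublet lag. Stationary SDs are
  $\sigma_\mathrm{long} = 0.177$ µm and $\sigma_\mathrm{short} = 0.085$ µm —
  calibrated as plateau$/\sqrt 2$ from the ~0.25 / ~0.12 µm RMSD plateaus —
  with correlation time $\tau = 3$ min, chosen so the RMSD saturates well
  inside the 20-min observation window. Because the home point tracks
  ±L(t)/4 of a growing cell, the clusters acquire a small outward net
  average movement without a separate drift parameter. Single-round
  bookkeeping: a cluster carried across division (home then at the
  daughter's mid-cell, where termination occurs) is ended no later than the
  daughter's own initiation.
* **Locus state machine.** The labelled locus rests at a home point that
  interpolates from the quarter position (α = 0) to the new pole (α = 1),
  mirrored in a configurable fraction of cycles to emulate the two
  chromosome arrangements seen at slow growth. Starting 10 min before the
  cell reaches $A(\alpha)$ (scaled by the cycle's initiation noise), the
  home point ramps to the nearest replisome; the locus then dwells at the
  replisome for 5 min with replisome-level confinement, forks, and the two
  copies ramp over 10 min to their positions in the prospective daughters.
  Terminus-style loci instead anchor both copies at mid-cell. The 10-min
  lead and segregation times and the 5-min colocalization dwell are order-of-
  magnitude choices consistent with transitions visible over a few area
  bins; none is a printed value.
* **Short-time-scale movement.** The 1-s doublet position displaces the
  frame position by a per-axis Gaussian step whose SD is a property of the
  state: 0.05 / 0.03 µm (long/short) for an unreplicated locus and, while
  colocalized with the replisome, exactly the replisome confinement
  process's own 1-s displacement SD $\sigma\sqrt{2(1-e^{-\Delta/\tau})}$
  (≈ 0.019 / 0.009 µm). Decoupling the 1-s step from the 1-min confinement
  reflects the subdiffusive character of chromosomal loci — their 1-s
  motion is much smaller than their minute-scale excursions.
* **Observation model.** Foci are observed every minute with a paired frame
  1 s (1/60 min) later; isotropic Gaussian localization error (0.02 µm per
  channel) and a 2% miss probability are applied; the locus channel is
  passed through a chromatic affine map (default translation
  (0.08, −0.05) µm) that the landmark registration must undo, with a grid of
  fiducial beads emitted alongside.

What the generator does **not** emulate: pixel-level images and spot
detection (foci are born localized), photobleaching and blinking,
overlapping replication rounds and multifork chromosomes, cohesion of sister
loci beyond the fixed colocalization dwell, the mechanistic basis of
terminus anchoring, and the terminus anomaly seen at fast growth. Passing
tests therefore certify the analysis chain — coordinate geometry, linking,
drift-corrected RMSD, displacement and distance statistics, registration —
under a faithful but idealized generative picture, not the image-analysis
front end.

## Analysis design choices

Several procedural points are genuinely open in this kind of analysis; the
package resolves them as follows.

* **RMSD reference.** The RMSD is referenced to each trajectory's position
  at its own initiation event (not a consecutive-lag MSD), matching the
  question "how far does the replisome get from where replication started".
  Trajectories are truncated at the division of the initiating cell;
  trajectories shorter than the window keep missing tails rather than being
  dropped.
* **Drift subtraction.** The upper and lower replisome clusters are
  corrected separately (so their mirrored outward drifts are each removed
  with the correct sign): per cluster and per aligned time point the
  across-trajectory mean displacement-from-start is subtracted. After
  correction the ensemble mean is identically zero at every lag; time points
  with fewer than two trajectories reuse the last valid mean and are
  flagged. The plateau is the mean RMSD over lags 10–20 min, and its quoted
  error is the mean of the per-lag SEMs — the same trajectories enter every
  lag, so averaging correlated lags must not shrink the error by
  $\sqrt{K}$.
* **Linking and pairing.** Both the frame-to-frame linker and the
  two-channel pairing solve a gated minimum-total-distance one-to-one
  assignment. "Closest to each other" pairing rules are operationalized as
  optimal assignment, which subsumes mutual-nearest pairing in the generic
  case and resolves conflicts consistently; the objective charges half the
  gate per unmatched particle, so every pair cheaper than leaving both sides
  unmatched is formed and pair count is maximized before total distance is
  minimized. Instances with up to 12 foci are solved exactly by dynamic
  programming over column subsets; larger instances (never produced by the
  generator) fall back to global-nearest-first. The linker bridges up to 2
  missed frames with the gate scaled by the gap; doublet partners are linked
  with a tighter 0.3 µm gate since little motion accrues in 1 s.
* **Initiation detection.** A trajectory start is an initiation candidate if
  the trajectory lives ≥ 5 frames and no other replisome trajectory had a
  detection within 0.5 µm in the preceding frame (suppressing re-detections
  after transient splitting). Since one initiation spawns two clusters,
  qualifying starts in the same cell within one frame are merged into a
  single event carrying both trajectory ids.
* **Binning.** Spatial bins are 0.1 µm and area bins 0.25 µm² everywhere,
  shared between location histograms, displacement maps and profiles, with
  left-closed right-open intervals; empty bins are reported as empty rather
  than dropped. Spatial-map bins are reported only when they hold strictly
  more than 4 displacements. Foci that fall outside the cell outline due to
  localization noise are kept — clipping would bias the fitted SDs.
* **Displacement minima.** The per-area-bin mean profile is smoothed with a
  3-bin moving average (partial windows at the edges) before the argmin is
  taken; the minimum is reported as the bin center with a 200-resample
  within-bin bootstrap percentile interval. On a dip confined to a single
  bin the moving average can shift the argmin by one bin, which is the
  accuracy the procedure claims (minima are read at bin resolution).
  A flat profile has no defined minimum and is flagged, not guessed.
* **Gaussian location fits.** Axis-independent maximum-likelihood Normal
  fits (sample mean and ML SD) per cluster and area bin, with clusters
  assigned by the sign of the relative long-axis position; cluster-bins with
  fewer than 10 positions are flagged invalid and excluded from averages.
  $\sqrt 2 \times$ the average fitted SD is the expected RMSD plateau of a
  particle whose position decorrelates within the window, which is what
  makes the location-distribution width and the RMSD plateau directly
  comparable.
* **Registration.** The channel map is a least-squares 2D affine fit to
  bead landmarks with a leave-one-out residual RMS; degenerate (collinear or
  < 3 bead) inputs are errors, not warnings. Distances are 2D Euclidean in
  the registered frame. Whether pairing should be gated is not observable
  from the data we emulate; the default gate is 1 µm and configurable.
* **Configuration and reproducibility.** The pipeline configuration is
  plain-text YAML with unknown keys rejected; all tables are CSV with fixed
  schemas, written with a shortest-round-trip float writer and read back
  with `strtod`, so write–read round trips are bit-exact. Each lineage draws
  from its own substream derived from the root seed, so enlarging a dataset
  does not perturb existing lineages, and identical config + seed reproduce
  every output byte for byte.

## Problem sizes used in the validation suite

The recovery checks run the full pipeline on 48 lineages observed for 330
min (about 320 cell cycles, giving > 500 aligned replisome trajectories —
comfortably above the ≥ 457 used for the reference RMSD), and three 12-lineage
runs for the per-locus displacement-minimum recovery at α ∈ {0, 0.5, 1}.
Property checks (closed-form RMSD agreement, assignment-oracle equality,
drift annihilation, round trips) use small constructed instances.

## Known limitations

* The generator's locus home-point geography (quarter position to new pole,
  linear in α) is a qualitative reading of published location histograms;
  real arm loci need not interpolate linearly.
* Initiation detection assumes the replisome label produces no persistent
  foci between rounds; with a label that is visible between rounds the
  trajectory-start criterion would need an intensity gate.
* The displacement-minimum locator reports bin centers; sub-bin minima
  locations are outside its resolution by design.
* In the single-round regime the initiation-size distribution is censored
  from below by birth size; at growth conditions where birth and initiation
  sizes overlap strongly, the detected mean initiation area overestimates
  the underlying threshold.
* The mean-reverting confinement model is the simplest stationary process
  with a tunable SD and correlation time; it reproduces plateaus but not,
  e.g., anomalous-diffusion exponents, which the package deliberately does
  not fit.
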