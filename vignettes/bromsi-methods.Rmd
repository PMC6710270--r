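---
title: "Screening brominated indole metabolites in MSI data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening brominated indole metabolites in MSI data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bromsi)
```

## The problem

Orally delivered brominated indoles — 6-bromoisatin (6Br, C8H4BrNO2), its
natural-extract relatives tyrindoleninone (C9H6BrNOS) and the dimeric
6,6'-dibromoindigo / 6,6'-dibromoindirubin pair (C16H8Br2N2O2) — are
transformed in the gut into a family of metabolites, many of them too
insoluble to survive conventional extraction. Mass spectrometry imaging of
gastrointestinal sections can see these species *in situ*, but they sit in a
dense forest of endogenous ions. Bromine rescues the search: its two stable
isotopes, 79Br (50.69%) and 81Br (49.31%), are nearly equally abundant and
1.998 Da apart, so a compound carrying one bromine shows an unmistakable
~1:1 doublet and a compound carrying two shows a 1:2:1-like triplet
(0.2569 : 0.4999 : 0.2431). `bromsi` implements the full screening pipeline
around this tracer: exact-mass chemistry, spectral preprocessing, pLSA
tissue segmentation, halogen-signature detection with lipid de-replication,
spatial co-localisation and library annotation — plus a synthetic phantom
generator that provides ground truth for every stage.

## Exact-mass chemistry

All masses derive from one embedded isotope table (IUPAC monoisotopic
masses and abundances) plus the electron mass, 0.00054858 Da. Singly
charged cation m/z always includes the electron: that convention reproduces
the caesium iodide calibration series [Cs(n+1)In]+ — 132.90490, 392.71483,
652.52475, 912.33468, 1172.14460, 1431.95453 — to five decimal places, so
it is demonstrably the convention used in practice. Hydride abstraction
[M-H]+ is modelled as loss of one hydrogen *atom* plus one electron, which
places the 6Br cation at m/z 223.9342, within 1.5 ppm of the
ESI-ultra-high-resolution value of 223.9345.

Isotope envelopes are computed by iterated convolution of per-element
distributions (binary exponentiation for element powers). Two numerical
choices matter:

* **merge tolerance, 0.01 Da** — isotopologues closer than this are merged
  by abundance-weighted centroid. TOF instruments cannot resolve isotopic
  fine structure (e.g. 13C vs 15N substitutions near M+1), so carrying it
  would be false precision.
* **pruning threshold, 1e-4 relative abundance** (configurable in
  `[0, 0.01]`) — tails below this are dropped *after* bookkeeping, so the
  retained abundances plus the recorded `pruned` loss always sum to 1.

## Spectral preprocessing

The processing chain mirrors standard TOF-MSI practice: TopHat baseline
subtraction, TIC-preserving resampling, peak picking, external quadratic
calibration.

* **TopHat** subtracts the morphological opening (erosion then dilation
  with a flat structuring element). Window default **5 Da**: much wider
  than a peak (FWHM ~0.1–0.3 Da), much narrower than baseline undulation.
  The opening is a lower envelope, so output is non-negative, bounded by
  the input, and idempotent. The running extrema use an O(n) van Herk
  kernel in C++.
* **Resampling** treats the profile as a histogram on bins delimited by
  axis midpoints and redistributes mass by bin overlap (linear
  interpolation of the cumulative mass function). Total ion current is
  conserved to floating-point accuracy whenever the new axis covers the old.
* **Peak picking** keeps local maxima whose apex rises at least `snr_min`
  noise units above the running median. Noise is 1.4826 × the median
  absolute deviation from the running median in a sliding 101-bin window —
  scale-invariant by construction. Signal is measured *above the running
  median* because the opening's lower-envelope property leaves residual
  noise on a small positive pedestal; measuring from zero would inflate
  SNR. A noise floor of 1e-9 × max intensity (also scale-invariant) stops
  float-level ripple on noiseless Gaussian tails from acquiring unbounded
  SNR. Centroids are intensity-weighted means over the samples above half
  apex height; equal-height plateau maxima resolve to the lower m/z.
* **Calibration** fits calibrated = c0 + c1·mz + c2·mz² by least squares on
  a centred/scaled predictor (for conditioning), against the six CsI
  cluster references by default; references are matched to the nearest
  observed peak within 0.5 Da. Identity input recovers (0, 1, 0) to
  machine precision; an exactly quadratic synthetic distortion is recovered
  to better than 1e-9.

## pLSA segmentation

Pixels are documents, binned peak centroids (0.1 Da bins) are words, and
rounded intensities are pseudo-counts: the multinomial pLSA model. EM
alternates the posterior responsibility of each topic for each
(pixel, peak) pair with re-estimation of P(topic|pixel) and P(peak|topic),
implemented as collapsed matrix updates so each iteration is two small
matrix products. The log-likelihood is non-decreasing — asserted at every
iteration, with 1e-9 relative slack for floating-point rounding near
convergence.

Choices: `k = 6` by default, mirroring the six histological layers of a
gut cross-section (lumen, stratified squamous epithelium, mucosa,
muscularis mucosae, sub-mucosa, muscularis); random seeded initialisation
with 5 restarts keeping the best likelihood; convergence at relative
log-likelihood change < 1e-6 or 500 iterations; zero-TIC pixels excluded
from fitting and labelled −1. Labels are the per-pixel argmax of
P(topic|pixel), ties toward the lowest topic index, ids 0..k−1.

## Halogen screening and de-replication

For every picked peak, partners are sought at +1.99795 Da (and +3.99590 Da
for di-Br) within `tol_mz`. The member intensity vector is scored against
the Br template by cosine similarity; candidates scoring at least
`score_min` are kept, and each peak may belong to only one candidate, with
di-Br claims taking precedence over mono-Br (then score) so a clean triplet
never also yields its internal pairs.

* **`tol_mz` = 0.05 Da**: TOF-scale accuracy; with 0.05 Da profile bins the
  centroid scatter is a few hundredths of a Da. Configurable down to 0.005
  for exact-mass peak lists.
* **`score_min` = 0.95**: in simulation, Br1 doublets and ordinary
  carbon-isotope envelopes separate cleanly at this value — an M/M+2
  carbon pair at a C40 lipid's 8% ratio scores ~0.77 against the Br1
  template.
* **De-replication window 0.15 Da**, wider than `tol_mz` on purpose: where
  several lipid species blend within one peak width (FWHM reaches ~0.3 Da
  at m/z 1100), the apparent centroid can sit up to roughly half a width
  off any single species' position. A candidate is flagged `lipid` when
  all member peaks coincide with known lipid isotopologues, or when a
  matching lipid's own isotope envelope explains the intensities better
  than the Br template. Flagged candidates are retained in all outputs
  with their status — nothing is silently dropped.

These tolerances are simulation-justified: across 40 independent phantom
seeds with per-pixel spike SNR around 10–15, the screen attains sensitivity
1.0 for all spiked mono- and di-Br compounds with zero false positives
after de-replication.

## Co-localisation, annotation, fold changes

Candidate ion images (±`tol_mz` windows) are correlated pairwise (Pearson
over pixels; zero-variance images are an error, not a silent 0) and grouped
by connected components of the r ≥ 0.7 graph — single-linkage behaviour,
with groups numbered by lightest member so input order is irrelevant.

Annotation matches each candidate's lightest peak against every library
formula × adduct (and mass-only library entries against their stated m/z),
reporting *all* matches within tolerance ranked by |ppm|. Isobars are never
collapsed: the dibromoindigo/dibromoindirubin pair (identical formula) is
always reported together. Unmatched candidates receive sequential M-series
placeholder names. Tolerance is 10 ppm for exact-mass peak lists and
200 ppm for TOF/DIOS-grade data (0.05 Da bins limit centroid accuracy to a
few tens of ppm at m/z 200–500); both live in the config.

Region fold changes are TIC-normalised: (candidate intensity / ROI TIC)
in one region divided by the same in another. Sections acquired separately
need this normalisation; its known cost is a small compression of the true
ratio when the regions' total matrix content differs, which is visible in
the closed-loop test below (1.98 recovered for a designed 2.0 when the
shared matrix dominates TIC).

## The synthetic phantom: what it emulates, what it does not

`make_phantom()` builds concentric elliptical bands with a seeded angular
wobble — lumen innermost through muscularis outermost — approximating a gut
cross-section at 60 µm pitch; the default 64 × 64 grid (4,096 pixels)
exceeds the >3,000 spectra of one real section. `simulate_dataset()` gives
every pixel baseline (exponential decay + slow sinusoid), a region-specific
lipid background, spiked compound envelopes, and noise:

* ~40 lipid-like species in m/z 400–1100 across five TLC-resolved classes,
  each region boosting its own subset (5× over a 0.3 shared base) — the
  compositional contrast pLSA exploits, standing in for real tissue-layer
  lipid profiles;
* engineered **decoy pairs**: co-located species ~1.998 Da apart at ~1:1
  intensity, flagged in ground truth — exactly how low-abundance lipid
  pairs mimic di-Br envelopes;
* mono- and di-Br spikes confined to the lumen (the distribution observed
  for brominated metabolites in the stomach), full envelopes from the
  isotope engine, per-pixel log-normal abundance (σ = 0.3 — positive and
  right-skewed like real ion counts; no distribution is published, so this
  is an engineering choice);
* Gaussian peak shapes with FWHM = 0.12 Da × √(m/z / 200); additive
  Gaussian noise (σ = 0.5 counts by default), optional shot noise; a linear
  ±20 ppm mass drift across columns to exercise calibration;
* a uniform 0.05 Da axis over 20–1500 Da: ≥10 samples per Da near m/z 225,
  resolving the 1.998 Da Br spacing.

A fixed seed yields a bitwise-identical dataset. Ground truth records every
spiked isotopologue's theoretical m/z, regions and intensity, the lipid
table with decoy flags, and the label map.

**What passing on the phantom does not show:** real DIOS/TOF data have
detector saturation, isotopic fine structure, correlated (non-Gaussian)
chemical noise, tissue-section artefacts and registration error, none of
which are simulated. Phantom results validate the pipeline's logic and its
tolerances' internal consistency, not instrument-specific performance.

## Problem sizes used by the test suite

The suite validates segmentation on the default 64 × 64 phantom (fixed
seed, k = 6; adjusted Rand index against ground truth ≥ 0.8, in practice
1.0) and EM monotonicity over 20 seeds on the same data cube. The 20-seed
screening study runs on 16 × 16 phantoms with the full 20–1500 Da axis and
spike areas set so ROI-summed SNR is at least 10 — small enough to run the
whole study in a few minutes while keeping every structural feature of the
default phantom (all six regions, full lipid background, decoys, drift).

## Known limitations

* The pLSA variant here is the plain multinomial model with random
  restarts; commercial implementations may regularise differently, so
  equivalence holds at the level of the model class.
* Chlorine and other halogen templates are an extension point, not
  implemented; overlapping-envelope deconvolution is out of scope.
* Fold-change values are TIC-normalised by definition; when comparing
  regions whose total matrix content differs strongly, the reported ratio
  compresses toward 1 (see above) — interpret accordingly.
* The imzML layer covers continuous and processed modes with uncompressed
  32/64-bit float arrays, the subset this pipeline reads and writes.
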