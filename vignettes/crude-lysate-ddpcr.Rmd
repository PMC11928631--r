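---
title: "Methods: Poisson quantification and validation for crude-lysate ddPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson quantification and validation for crude-lysate ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletquant)
```

## The measurement problem

Droplet digital PCR (ddPCR) partitions one reaction into tens of thousands
of water-in-oil droplets, runs an endpoint PCR in each, and reads a
two-channel fluorescence amplitude per droplet. A droplet that received at
least one copy of the target amplifies and ends bright; a droplet that
received none stays dim. Because copies distribute across droplets
essentially independently, the number of copies per droplet is Poisson,
and the fraction of *negative* droplets identifies the mean loading
$\lambda$ (copies per droplet):

$$\hat\lambda = -\ln\!\left(\frac{N_{neg}}{N}\right), \qquad
  C = \frac{\hat\lambda}{V_{droplet}}\ \text{copies}/\mu L .$$

This package implements that estimator and everything around it for a
demanding use case: quantifying rare targets — T-cell receptor excision
circles (TRECs), episomal DNA loops whose per-cell frequency tracks thymic
output — directly in *crude cell lysate*, skipping DNA extraction so that
samples of only a few hundred cells are usable. The second channel carries
a reference gene (RPP30-style, one copy per haploid genome) that counts
cell equivalents, so results are reported as targets per cell.

Two package-level constants deserve comment:

* **Droplet volume, 0.70 nL.** Optical microscopy of droplet monolayers
  consistently yields ~0.70 nL rather than the 0.85 nL assumed by the
  vendor software. Since concentration is $\lambda/V$, this is a ~21%
  systematic effect on every reported concentration. The volume is a
  single configurable value (`droplet_volume_nl`) converted from nL to µL
  in exactly one place (`to_concentration()`).
* **Replicate merging.** A rare target in a limited sample is best
  screened by splitting one lysate across several reactions and *summing
  the droplet counts* before the Poisson estimate (`merge_counts()`),
  e.g. four ~20,000-droplet wells into ~80,000 screened partitions.
  Because the estimator depends only on $(N_{neg}, N)$, merging counts is
  *exactly* equivalent to pooling the droplet tables — an identity the
  test suite asserts.

## Classification model

Thresholds are derived from blank wells (no-template controls, NTC, and
target-free cell-lysate controls, CLC): per channel,
`threshold = pooled blank mean + k × SD` with default `k = 7`. The choice
of 7 is deliberately conservative: under the Gaussian cluster model the
per-droplet false-positive probability is `pnorm(-7) ≈ 1e-12`, so even
dozens of 20,000-droplet blank wells contain no positive droplet and the
limit of blank is 0 — while the threshold still sits far below a positive
cluster placed several thousand amplitude units higher. `k` is a config
knob; practitioners who set thresholds manually can reproduce any placement
between the clusters.

Classification details that matter for rare targets:

* a droplet exactly **at** the threshold is negative (strict `>`) — the
  conservative tie rule;
* manual gating of artifact clusters is replayed as explicit, auditable
  axis-aligned `exclusion_region()`s, never automatic outlier removal;
  excluded droplets leave `n_total` and are tallied separately;
* wells must have **more than 10,000** accepted (post-exclusion) droplets
  to enter analysis (`qc_filter_wells()`, strict inequality).

## Uncertainty

The delta method on the binomial negative fraction $p = N_{neg}/N$ gives
$SE(\hat\lambda) = \sqrt{(1-p)/(Np)}$ and a normal 95% CI, floored at
zero on the concentration scale. Two boundary cases are handled
explicitly rather than silently: a **saturated** well ($N_{neg}=0$) is an
error ("above dynamic range"), and a fully negative well ($N_{neg}=N$)
reports concentration 0 with a one-sided exact upper bound
$\lambda_{up} = -\ln(0.05)/N$ (the largest $\lambda$ under which an
all-negative well has ≥ 5% probability).

The targets-per-cell ratio divides target concentration by cells/µL
(reference concentration over `ref_copies_per_cell`). The reference gene
is typically 10³–10⁴-fold more abundant than the target, so by default
the ratio CI propagates only the target channel; the full delta-method
ratio CI is available via `propagate_ref = TRUE`. `ref_copies_per_cell`
defaults to 2 (diploid autosomal single-copy gene) — the conversion from
genome equivalents to cells requires *some* factor and 2 is the
biological default; it is configurable because cell lines with copy-number
alterations violate it.

## Validation statistics

* `cv_percent()` uses the sample SD (n−1); this convention reproduces a
  published eight-sample intra-assay replicate panel (shipped in
  `inst/extdata/`, accessor `intra_assay_replicates()`) to its printed
  per-sample CVs and grand-mean CV.
* `limit_of_blank()` is mean + 1.645 SD over blank-reaction
  concentrations; `limit_of_detection()` adds 1.645 SD of the lowest
  tested level to the LOB; `limit_of_quantification()` selects the lowest
  level with CV ≤ 35% (inclusive at the boundary) and reports an explicit
  "not reached" rather than extrapolating.
* LOD/LOQ replicate statistics can be computed on copies/reaction or
  targets/cell (`loq_scale`); both conventions appear in practice, so the
  scale is explicit in the report rather than implied.
* A *detection*, for hit-rate purposes, is a merged sample group with at
  least one positive target droplet after exclusions. The probit dose
  response is fitted by maximum likelihood on `log10(concentration)` only
  when rates vary; an all-0/all-1 table has no identifiable slope and is
  flagged `"degenerate"` instead of forcing a fit.

## Method agreement

`linear_fit()` (OLS with a t-based slope CI and the CI-contains-1
accuracy check), `spearman_rho()` (mid-ranked ties) and `bland_altman()`
cover the linearity/accuracy/agreement trio. The Bland-Altman difference
direction is fixed and labelled as `test − reference`; sign conventions
are a classic source of silent confusion in agreement analyses, so the
direction string travels with the result object.

## Droplet-volume imaging

Droplets in a monolayer present their equatorial cross-section.
`segment_droplets()` follows the standard particle-analysis recipe
(global Otsu threshold, hole filling, connected components via EBImage,
then area and circularity filters), and converts each area to an
equivalent diameter $d = 2\sqrt{A/\pi}$ and sphere volume
$(\pi/6)d^3$ — a chain that is exactly invertible on analytic circles.
Defaults: when no absolute area filter is supplied, components outside
0.25–2× the median area are rejected (debris and merged doublets);
touching droplets are excluded by the circularity filter rather than
split by watershed, which matches spaced monolayer imagery. Featureless
images are recognized by a foreground/background contrast floor (0.2
grey levels) and return an empty measurement table with a warning
instead of spurious components.

## What the simulator emulates — and what it does not

`simulate_well()` draws a droplet count `round(Normal(mean, SD))`,
truncated-normal per-droplet volumes (default 0.70 ± 0.022 nL, the
measured lysate droplet-volume spread), independent Poisson copy counts
per channel with per-droplet mean `conc × V_i`, and Gaussian amplitude
clusters with an optional uniform "rain" fraction between the cluster
means. Two crude-lysate artifacts are reproduced phenomenologically: the
*no-viscosity-breakdown* pattern (a diagonal smear from a shared positive
offset on both channels plus a droplet-count reduction) and a *shifted
double-negative sub-cluster* in Ch1. Their geometry is not calibrated to
any instrument — the knobs (`fraction`, `scale`, `reduction`, `offset`)
are free config — because no quantitative description of these artifacts
exists; they are there so exclusion-region replay and QC behavior can be
exercised.

Design choices, made once:

* **Poisson-per-droplet loading** (independent across droplets and
  channels) rather than multinomial allocation of a fixed copy pool: the
  standard dPCR assumption, indistinguishable at rare-target scale, and
  the same model the estimator inverts. Restriction digestion of the
  template is modeled only as this independence (no linked
  co-encapsulation).
* **Dilution-series convention:** `cells_per_well` counts the cells
  captured in a well's droplets, so a level at ratio `r` loads an
  expected `r × cells_per_well` target copies into the well's droplets
  (e.g. 0.0003 × 2500 = 0.75 copies/well; a four-well merged sample
  expects ~3 copies, giving a ~95% theoretical hit rate, `1 − e^{−3}`).
* **Amplitude defaults** put clusters ≥ 8 SD apart (negatives 1000 ± 100,
  positives 8000/7000 ± 300), with 1% rain. Real plates can be messier;
  the rain fraction and cluster parameters are the dials to stress the
  classifier.
* **Determinism:** every well derives all draws from its config seed, so
  a plate regenerates bit-identically; derived per-well seeds stay within
  32-bit integer range.

What passing tests on these simulations *do not* show: robustness to
non-Gaussian amplitude clusters, drifting baselines, droplet-size-
dependent amplitudes, inter-channel crosstalk, or instrument-level
"accepted droplet" filtering — real-data phenomena outside the generative
model. Conclusions about real plates rest on the estimator algebra and
the classification contracts, which are exact, not on the simulator.

## Numerical choices and degenerate inputs

* Thresholding with zero blank SD falls back to an absolute margin with
  a warning (degenerate but reachable with synthetic input).
* `limit_of_quantification()` requires levels sorted by decreasing
  concentration and errors otherwise, rather than silently re-sorting.
* Zero/constant series are errors in `spearman_rho()` and `linear_fit()`
  (undefined), not NA propagation.
* Mixed-group merging is an error: merging across samples is always a
  bug, never a convenience.

## Problem sizes used in the shipped analyses

The bundled analysis scripts and checks simulate at the scale of a real
plate where that is cheap (wells of ~20,000 droplets; 22 blank wells;
four dilution levels in triplicate with four merged wells each; 200-well
recovery studies; 100-replicate rare-event hit-rate studies; 300-disc
micrographs at 1 µm/px on a 3200² canvas), chosen as representative of
the assay geometry while keeping the full suite comfortably fast on a
laptop.

## Known limitations

* Volume heterogeneity enters the estimator only through the fixed point
  value of `V_droplet`; no multi-volume partition correction is applied
  (the induced bias at these volume CVs is ≪ 1%).
* The LOB→LOD scale conversion when the LOB is nonzero and the LOQ scale
  is targets/cell divides by the lowest level's measured cell density; a
  zero LOB (the regime this assay targets) is scale-free.
* No Deming/Passing–Bablok regression and no repeated-measures
  Bland-Altman; OLS with a slope-CI check mirrors common practice for
  these designs.
* The imaging module does no illumination correction or sub-pixel edge
  fitting; at 1 µm/px the pixelation error on a ~110 µm disc is well
  under the 5% volume tolerance used in its checks.
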