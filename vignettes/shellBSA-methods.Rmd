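---
title: "Methods: whole-shell thickness measurement and four-statistic bulked-segregant scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-shell thickness measurement and four-statistic bulked-segregant scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(shellBSA)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
knobs matter, and what a passing test suite does and does not establish.

# The phenotype: whole-shell thickness from a binary mask

## Model

The input is a pre-segmented binary mask of a shell cross-section — one
connected foreground component with exactly one hole, i.e. a ring whose
outer boundary is the exocarp outline and whose inner boundary is the
mesocarp outline. Segmentation itself (from a colour scan) is out of
scope: in practice the shell is cut out by hand with a lasso tool and
the package starts from the resulting mask.

The thickness at a point of the outer boundary is the minimum Euclidean
distance from that point to the inner boundary; whole-shell thickness
(PST) is the arithmetic mean of this local thickness over points sampled
uniformly in arc length along the outer boundary, converted to mm by the
pixel scale. Averaging over the whole outline is the point of the
method: shells are irregular, so a caliper reading at one arbitrary spot
is a poor estimator, and contact measurement can deform the shell.

## Numerical choices

* **Contour tracing.** Both boundaries are traced at iso-level 0.5 with
  `grDevices::contourLines` (a marching-squares equivalent), giving
  closed sub-pixel polylines, normalized counter-clockwise. Foreground
  topology (one 8-connected component, one hole by 4-connected
  background labelling) is validated first, so failures name the actual
  component/hole count.
* **Sawtooth regularization.** The 0.5-level contour of *binary* data
  carries a half-pixel sawtooth. Its outward bumps bias minimum
  distances systematically downward (~0.2 px) and inflate perimeters by
  several percent. Measurement wrappers therefore smooth each contour
  with a circular moving average spanning ~7 px of arc
  (`smooth_px = 7`). For a curvature radius R the window shortens the
  radius by about s²/(24R) — under 0.03 px for the shapes of interest —
  so the correction removes the artefact without moving the boundary.
  `extract_contours()` defaults to the raw iso-lines; pass `smooth_px`
  explicitly when measuring.
* **Sampling density.** The outer contour is resampled at equal arc
  steps, `round(points_per_px × perimeter)` points with a floor of 64.
  The default `points_per_px = 3.183` yields ≈2,000 points on a typical
  pod outline (perimeter ≈ 630 px), matching the density the method was
  designed around; the suite checks that beyond ~500 points the mean
  changes by < 0.2%, so the default is comfortably converged.
* **Distances are point-to-segment**, not point-to-vertex: the nearest
  point on the inner polyline may fall inside a segment, and
  vertex-only search would couple the answer to vertex density. An
  exhaustive double-loop oracle checks exact agreement in the tests.
* **Pod geometry.** PA is foreground pixel count × scale²; PP is the
  (regularized) outer contour arc length × scale. PL/PW are not defined
  in the field's informal usage, so the package defines them as the
  bounding-box extents after rotating the silhouette so its principal
  axis (first PC of foreground pixel coordinates) is horizontal, with
  PL ≥ PW enforced. Rotation invariance of this definition is tested to
  ±2 px.
* **Scale** (mm/px) must be supplied by the caller; there is no
  default, because scanner DPI varies and a wrong silent default would
  corrupt every downstream statistic.

## The synthetic shell generator

`generate_shell_image()` draws an elliptical ring: outer semi-axes
(R, R(1−e)), inner boundary the same ellipse shrunk by the thickness in
both semi-axes, optional smooth per-angle radial jitter on both
boundaries, rasterized by the pixel-centre rule on a 512×512 canvas.
The reported ground truth ignores the jitter and is computed from the
generating geometry (exactly R−r for circles; by dense arc-length
sampling against the inner boundary for ellipses, which an independent
`optimize()`-based oracle confirms in the tests). What a green test
establishes is therefore accuracy on *smooth, ring-shaped, pre-segmented*
masks — not robustness to segmentation errors, touching structures, or
broken rings, which the module deliberately rejects with errors.

# The association scan

## Inputs and filtering

The scan consumes a 4-sample variant table — two parents and two bulks
with per-sample allele depths (VCF 4.x with GT/AD, parsed by
`VariantAnnotation`, or an equivalent TSV). Multi-allelic records and
records lacking depths are skipped with counts. A site is informative
iff both parents are homozygous for different alleles, QUAL ≥ 30
(configurable), and each bulk's depth lies in `[min_depth, max_depth]`
(default 10 to 3× the mean depth — the source protocol says only
"high-quality", so the cutoffs are explicit and configurable rather
than hidden). Indels are retained as biallelic sites. All coordinates
are 1-based inclusive, as in VCF.

## Orientation

Allele depths are oriented to the allele carried by the thick-phenotype
parent ("focal"), not to the reference genome. Published scans rarely
state their orientation, but only a parent-oriented index gives
Δ(SNP-index) a stable sign meaning: Δ > 0 is thick-bulk enrichment for
thick-parent alleles wherever the locus sits. The suite checks the
implied antisymmetry: swapping the parent labels negates Δ and signed
ED exactly and leaves G and Fisher's P untouched.

## The four statistics

With focal frequencies `f` (thick bulk) and `g` (thin bulk):

* Δ(SNP-index) `= f − g ∈ [−1, 1]`.
* `ED = √2·|f−g|`; `ED²` is the plotting scale, and `signed_ed =
  sign(f−g)·ED` preserves direction (published peak tables contain
  negative ED peaks, which raw ED cannot produce).
* `G = 2 Σ n ln(n/ê)` over the 2×2 table with independence expectations
  `ê`; zero cells contribute 0 (the x ln x → 0 limit) and no continuity
  correction is applied. G′ smooths G with a tricube kernel over
  physical distance within a half-window W/2 (W = 2 Mb by default);
  the SNP always includes itself, so an isolated SNP keeps G′ = G.
* Fisher's exact two-sided P uses the probability-mass convention (sum
  of hypergeometric outcomes no more probable than the observed table,
  relative tolerance 1e−7 — the convention of `stats::fisher.test`,
  which serves as an oracle in the tests). Accumulation is in log
  space, so `−log₁₀P` stays finite far beyond double underflow.

## Windows, thresholds, regions

* **Windows.** 2-Mb windows stepped every 10 kb, anchored at position 1
  and multiples of step + 1 (published region boundaries fall on this
  …0001 grid). Window means are unweighted; windows with fewer than
  `min_snps = 10` variants are masked (NA), not zeroed, so sparse
  regions cannot masquerade as nulls.
* **Δ thresholds** come from a null simulation in the classic
  pooled-extreme style: each bulk's true frequency is the mean of
  2 × bulk_size gametes, observed frequencies are binomial at the given
  depth, and symmetric (1±level)/2 quantiles of Δ form a
  depth-dependent band (interpolated at each window's mean depth). The
  band provably widens at shallow depth and collapses to pure
  bulk-sampling noise as depth → ∞, both checked.
* **ED²/G′/−log₁₀P thresholds** default to genome-wide empirical
  quantiles of the window statistic (type-7 linear interpolation),
  upper tail at the level, both tails for the signed ED track. This is
  an explicit design decision: published scans draw confidence lines
  for all four tracks without defining them; quantile lines are
  reproducible and assumption-free but are only calibrated when true
  signal occupies a small fraction of the genome (see *Limitations*).
* **Regions.** Windows beyond the 99% threshold merge when overlapping
  or abutting on the step grid; each merged interval carries its most
  extreme window mean as peak, with direction upper/lower by sign. The
  candidate regions are the maximal intervals covered by at least one
  significant interval of *every* method (all four by default;
  configurable k-of-4), with sizes reported as
  `(end − start + 1)/1e6` rounded half-up to 2 decimals. Unsigned
  tracks inherit region direction from the Δ track in the same span.
  Gene annotation is a ≥1-bp overlap against GFF3 gene features.

## The synthetic F2 world

The generator simulates the stated experiment: an F2 of 1,153
individuals from two inbred parents; each gamete recombines between
adjacent markers with the Haldane fraction at a constant 1 cM/Mb (no
map was published; only relative linkage matters for the tests), no
crossover interference. Phenotypes add per-QTL additive and dominance
effects (defaults 0.24 and 0.07 mm, the scale of a major shell QTL)
plus Gaussian noise scaled so the causal loci jointly explain the
configured heritability (default 0.3). Bulks are the 60 largest and 60
smallest phenotypes (ties by lowest index, selected disjointly —
mirroring direct selection of extremes; the published two-stage visual
pre-screen has no stated statistical effect to emulate). Pooled depths
are Poisson(85) per bulk and Poisson(43) per parent with equal DNA
contribution per individual, binomial allele draws, and a symmetric
per-read error `f(1−e) + (1−f)e` with e = 0.001. Whether the focal
allele is REF or ALT is randomized per site so orientation is always
exercised.

Two calibration/recovery worlds back the acceptance criteria:

* **Null calibration**: 20 QTL-free genomes (one chromosome × 2,000
  markers each); the fraction of windows beyond the 99% Δ band must
  stay ≤ 2.5%.
* **Recovery**: 20 single-QTL genomes at PVE ≈ 0.3 with 60+60 bulks at
  85×; the four-method intersection must contain the true locus in ≥
  19/20 seeds. This world uses **10 chromosomes** × 2,000 markers: the
  organism has 20 chromosomes (halved here purely for runtime), and a
  genome-scale null mass is what makes quantile thresholds meaningful.
  On a 2-chromosome toy genome the QTL's linked signal occupies ~25% of
  all windows, the 99% quantile lands inside the signal and slices only
  its drift-displaced top — a property of quantile thresholds on tiny
  genomes, not of the statistics.

What green tests establish: Mendelian segregation, seed-reproducibility,
correct variance partitioning, the documented tie and error contracts,
and end-to-end recovery under an idealized world — evenly spaced
markers, no genotyping error in parents, no alignment artefacts, no
segregation distortion, equal pooling. They do not establish robustness
to any of those real-data features.

# Degenerate inputs and tie-breaks

* Zero-depth bulks are errors at the statistics layer (they are
  filtered upstream; silently returning NaN would poison window means).
* Ties in nearest-segment search cannot change the distance value and
  are not broken explicitly.
* `select_bulks` breaks phenotype ties by lowest index and selects the
  high bulk first, so the two bulks are always disjoint even when many
  phenotypes are equal.
* Fisher's P is clamped to [1e−300, 1] only in the linear-scale column;
  `neg_log10_p` is computed in log space and never clamps.
* `region_size_mb` rounds half-up (floor(x·100 + 0.5 + ε)/100): base R's
  round-half-even would turn printed sizes like 0.965 the wrong way,
  and a 1e−9 epsilon guards binary representation of decimal ties.

# Limitations

* Quantile-based confidence lines for ED²/G′/−log₁₀P are
  signal-contaminated when trait-linked regions occupy a large genome
  fraction (small genomes, multiple strong QTLs). The Δ track's
  simulation band does not have this problem; a simulation strategy for
  the other tracks would need a model of within-window linkage and is
  not provided.
* The thickness pipeline requires a clean ring topology and rejects
  everything else; it does not attempt mask repair.
* TIFF masks are not supported (no TIFF reader among the package's
  dependencies); PNG and ASCII PGM are.
* Per-variant multiple-testing correction is intentionally absent: the
  scan thresholds smoothed tracks by confidence lines, not per-site
  FDR.
* Linkage-map construction, per-QTL PVE/LOD estimation and marker
  design are out of scope; only the physical-interval arithmetic of
  such downstream tables is covered (`region_size_mb`).
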