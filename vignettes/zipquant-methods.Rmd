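---
title: "Methods: quantifying GA-rich zipcode elements and peripheral RNA localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GA-rich zipcode elements and peripheral RNA localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipquant)
```

## The problem

mRNAs such as RAB13 are enriched at the protrusions of migrating cells, and
the site of their translation matters functionally. The cis-acting signal
is carried by the 3′UTR: short degenerate GA-rich motifs with the consensus
`RGAAGRR` (R = A or G), typically embedded in longer GA-rich stretches.
zipquant quantifies three layers of this biology: the sequence elements
themselves, the spatial distribution of RNA and of RNA–protein association
inside single cells, and bulk enrichment of transcripts in protrusion
fractions or immunoprecipitates.

## Sequence model and parameters

**Motif scanning.** A position matches when every residue falls in the
IUPAC set of the corresponding consensus character. All matches are
reported, including overlapping ones: published motif counts do not state
an overlap policy, and counting every occurrence is the conservative choice
that a brute-force oracle can verify exactly. Scanning is single-stranded —
these are mRNA elements, and a reverse complement is never taken
implicitly. Input sequences are upper-cased and U→T mapped; residues other
than A/C/G/T are rejected with the offending position named, rather than
silently matched or skipped.

**GA profile and GA-rich regions.** The %GA profile uses a 30-nt sliding
window (step 1), the window width used to plot GA content along the RAB13
3′UTR. A GA-rich region is operationalized as the maximal merged union of
30-nt windows whose GA fraction is *strictly* greater than 0.75 ("> 75%"
is read literally: a window at exactly 0.75 does not qualify), filtered to
a minimum length of 30 nt. A documented consequence of the union-of-windows
definition is that a region can extend a few nucleotides into flanking
pyrimidine sequence; the alternative (per-position GA runs) would not match
the windowed quantity that is actually plotted and thresholded.

**Coordinates.** All interval arithmetic is 1-based inclusive, which makes
construct descriptions exact: deleting nucleotides 204–211 removes 8 nt,
202–254 removes 53 nt. BED export converts to 0-based half-open. After a
deletion, annotations overlapping removed positions are dropped (with a
warning) and downstream annotations shift left by the removed length
upstream of them; a property test verifies that rescanning a deleted
sequence equals scanning the literally spliced string.

**Containment versus overlap.** Counting a motif as "inside" a GA-rich
region requires full containment of the 7-nt hit — the semantics of
"motifs found within regions". Antisense-probe classification instead uses
any-overlap (≥ 1 nt): a 25-nt probe only needs to cover part of a motif to
block it. A probe intersecting a motif hit is classified `overlaps_motif`
even when it also lies in a region.

**Enrichment.** Two-group enrichment uses the two-sided Fisher exact test
(summing hypergeometric probabilities no larger than the observed table's)
with Bonferroni correction `min(1, m·p)`. The number of tests `m` defaults
to 1 and is caller-supplied, since the appropriate family size depends on
how many motifs a user screens.

## Spatial statistics

**PDI.** The Peripheral Distribution Index implemented here is the second
moment of spot positions about the nucleus centroid, normalized by the
second moment of the cell mask about the same point. This reconstruction
satisfies the published anchors — uniform (diffuse) patterns give PDI ≈ 1,
peripheral patterns give high values, perinuclear patterns low values, and
all spots at the centroid give exactly 0 — and is invariant to translation
and isotropic rescaling of the scene. Whether the original calculator
measures distance from the nucleus centroid, cell centroid, or nucleus
boundary is not stated in the sources the package follows; the nucleus
centroid matches the perinuclear-versus-peripheral contrast the statistic
is used to draw, and the choice is documented rather than asserted as the
published formula. Analysis is 2D, matching the maximum-intensity
projection convention.

On a rasterized disk the reference moment carries a lattice-discretization
error (measured ≈ 3×10⁻⁴ relative at radius 200 px), so the closed-form
boundary-ring value of exactly 2 is met to 10⁻⁶ only in the continuum
evaluation; raster checks use a 5×10⁻³ envelope.

**Compartment bands.** The peripheral band is the set of cell pixels
within `w_p` of the cell boundary (Euclidean distance transform); the
perinuclear band is the set of extranuclear cell pixels within `w_n` of
the nucleus boundary. Band widths are not specified in the source
material; both default to 10% of the cell's equivalent radius
(`sqrt(area/π)`), are configurable, and overlapping bands are an error
rather than a silent reallocation. Spots and dots are assigned by
center-point membership — partial-overlap assignment was rejected because
it makes counts depend on dot segmentation details and breaks the
`n_peripheral + n_body = n_total` conservation that the counting is built
on.

**PLA dot calling.** Background is estimated per cell as the median and
MAD×1.4826 over the cell mask — robust statistics are required because the
dots themselves sit in the estimation region. A pixel is candidate signal
when *strictly* above `median + k_sd·SD` (default `k_sd = 3`, the
published "> 3 SDs above the background noise" rule); candidates are
grouped by 4-connectivity and components of at least `min_dot_area` px²
(default 4) become dots at their intensity-weighted centroid. A flat image
(SD = 0) is an error. Intensities are deliberately not summarized further:
PLA amplification is variable, so only counts are reported.

## Fractionation and RIP ratios

Ps/CB enrichment normalizes each gene to the geometric mean of a
caller-supplied housekeeping set within the same sample (the source
material names no specific housekeeping genes, so the set is a required
argument, never defaulted), then takes the Ps/CB quotient per replicate.
RIP enrichment corrects each eluate/input recovery by the spike RNA and
references the target to a control gene, making the result invariant to
any per-sample rescaling — a property the tests assert directly.
Replicates are aggregated as arithmetic mean ± s.e.m. to match the
reporting convention of the quantities being emulated; no log transform is
applied by default. Replicates with zero normalizer counts are excluded
with a warning; a zero denominator count flags that gene's replicate ratio
as undefined rather than propagating an infinity.

## What the synthetic data emulate

The generators define the package's study conditions and are fixed, not
tuning knobs:

- **UTR sets** emulate two groups of 3′UTRs (localized versus control).
  Background is i.i.d. uniform over A/C/G/T; lengths are uniform on
  300–1500 nt, a typical mammalian 3′UTR range. Planted motif copies per
  UTR are Poisson with rate 0.92 in the localized group — chosen so the
  probability of at least one copy is ≈ 0.60, the reported prevalence in
  protrusion-localized transcripts — and 0.1 in the control group. Planting
  overwrites background at uniformly chosen non-overlapping positions; the
  truth table records planted features only, and the random background can
  (and does) contain additional chance matches, which is why recovery tests
  check containment of truth in calls, not equality.
- **Cell geometries** are concentric or offset disks (defaults: radius
  100 px cell, 30 px nucleus in a 256 px image). Real cell outlines are
  irregular; the statistics under test are mask-agnostic, and disks make
  closed-form checks possible.
- **Spot patterns** use the minimal one-parameter radial family
  w(x) ∝ (d(x)/d_max)^β with d measured from the nucleus centroid:
  β = 0 uniform, β > 0 peripheral, β < 0 perinuclear. The emulated imagery
  describes these patterns only qualitatively, so the family was chosen for
  spanning the three regimes with one interpretable dial. For β < 0 the
  distance is clamped below at half a pixel so the weight stays finite.
  Spots are jittered uniformly within their pixel.
- **PLA images** are Gaussian background (clipped at 0) plus hard disks at
  `background_mean + dot_amplitude` — no point-spread convolution, because
  the dot calling being tested is threshold-based, not subpixel. Defaults
  (mean 100, SD 10, amplitude 100 = 10·SD, radius 2 px) put planted dots
  unambiguously above threshold so recovery is exact; planted centers keep
  a minimum separation of `2·radius + 2` px so truth dots remain
  individually resolvable. Spot-count and background levels in real PLA
  imagery are not described quantitatively in the emulated sources;
  defaults were chosen for test power, not realism.
- **Count tables** have expected count = baseline × size factor × ratio
  (enriched fraction) with optional Poisson noise, plus two housekeeping
  rows and a spike row at ratio 1. The default baseline of 1000 counts
  keeps the relative Poisson error near 3%, the regime where the estimator
  bias bound of 5% is meaningful.

Passing tests on these data show the estimators are correct on their
stated models; they do not show robustness to segmentation errors,
autofluorescence, optical crowding of smFISH spots, or UTR base
composition bias, none of which the generators emulate.

## Determinism and orchestration

Every generator takes an explicit seed and restores the caller's RNG
state. `run_pipeline()` drives all stages from one master seed, deriving
per-stage seeds by fixed offsets so adding or removing a stage never
perturbs another stage's draws; identical config + seed reproduces
byte-identical outputs, which the manifest's MD5 checksums make checkable.
Configurations are validated before any computation, with every offending
key listed at once.

## Problem sizes used in the test suite

Oracle-equivalence runs use 1,000 random sequences of length ≤ 200 nt;
Fisher enumeration covers all 2×2 tables with total n ≤ 30; PDI
monotonicity uses 2,000 spots at β ∈ {−2, 0, 2, 4} over 10 seeds; the
diffuse-PDI anchor averages 20 seeds of 500 spots; PLA null calibration
uses 100 seeded background-only images; Poisson-recovery checks use 50
replicates at baseline 1000. These sizes were chosen so each property is
measured well inside its stated tolerance.

## Known limitations

- The PDI formula is a documented reconstruction (anchors, not the
  original implementation, are the contract).
- GA-rich regions inherit the windowed definition's few-nt spillover into
  flanking sequence.
- Genome-scale motif prevalence and enrichment statistics depend on
  external transcript sets and annotation versions; the package provides
  the pipeline (`read_utr_fasta()` + `summarize_groups()` +
  `motif_enrichment()`) but ships no transcript database.
- No spot detection from raw FISH images (spot tables are input), no cell
  segmentation, no 3D statistics, no de novo motif discovery.
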