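---
title: "Spatial similarity networking for tandem MS imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial similarity networking for tandem MS imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnmsi)
```

## The problem

Mass spectrometry imaging (MSI) rasters a tissue section and records a mass
spectrum per pixel, but it cannot distinguish isomers, and isobars collapse
into one image even at high mass resolving power. Tandem MS imaging (MS²I)
adds, at every pixel, targeted MS² spectra of narrow precursor isolation
windows. A 0.7 Da window routinely co-isolates one to four precursors, so
the per-pixel MS² spectra are chimeric: a mixture of fragment peaks from
several molecules.

The deconvolution principle this package implements is spatial: product
ions derived from the same precursor inherit that precursor's spatial
distribution, so fragment ions can be grouped by the similarity of their
ion images rather than by their spectra alone. Spatial distribution plays
the role retention time plays in chromatography — an orthogonal dimension
alongside accurate mass and fragmentation.

## Spatial similarity networking (SSN)

For each isolation window, every product ion $k$ is reconstructed into an
image with pixel intensities $x_i^{(k)}$, $i = 1 \dots P$ over the $P$
pixels acquired under that scan filter. Pairwise spatial similarity is
scored with one of three metrics:

* cosine similarity
  $S(x, y) = \sum_i x_i y_i \,/\, \left(\sqrt{\sum_i x_i^2}\,\sqrt{\sum_i y_i^2}\right)$,
  which is independent of absolute intensity;
* the sum of squared errors $\mathrm{SSE}(x, y) = \sum_i (x_i - y_i)^2$;
* the mean of squared errors $\mathrm{MSE} = \mathrm{SSE}/P$.

SSE and MSE account for absolute intensity, which is informative within
one dataset but makes thresholds abundance-dependent; cosine is the
default because it transfers across acquisitions. An undirected graph is
built with product ions as nodes and an edge wherever the score passes the
threshold $\tau$ (score $\ge \tau$ for cosine, $\le \tau$ for SSE/MSE; ties
inclusive so the rule is a closed condition). Connected components of this
graph are the clusters; each product ion belongs to exactly one cluster by
construction, and unclustered ions are kept as flagged singlets rather
than discarded — low signal-to-noise ions that fluctuate across pixels
legitimately end up there.

The *coherent* variant first pools every image into non-overlapping
$p \times p$ patches (mean or median over the valid pixels of the patch)
before scoring. Pooling emphasizes regional coherence and suppresses
localized noise such as isolated hot pixels, which can otherwise cut the
correlation between images that agree everywhere else; $p = 1$ reduces to
the plain pipeline.

Each cluster is reassembled into a deconvoluted MS² spectrum (one peak per
member at its target m/z, intensity = mean image intensity, base peak
scaled to 100), which can be compared with an authentic standard via
`compare_to_reference()` using a 1 %-of-base-peak floor on the reference
side. Reproducibility across replicate datasets is quantified with the
Jaccard index of the replicate cluster sets, ions matched across datasets
greedily by nearest m/z; both the n-way intersection-over-union and the
mean of pairwise indices are reported, since either convention is in use.

## Parallel image acquisition (PIA) model

A high-resolution FT scan uses only a short ion accumulation out of a long
transient (defaults 5 ms of 1024 ms), so the fraction of the incoming ion
current the FT channel uses is `accumulation / scan time` — under 0.5 %,
leaving over 99.5 % available to parallel ion-trap MS² scans.
`acquisition_config()` captures the timing and geometry; the derived
arithmetic is:

* coverage: $N$ inclusion lists × $W$ windows per list distinct isolation
  windows (defaults 4 × 27 = 108);
* geometry: cycling $N$ lists along the scan (x) direction multiplies the
  MS² x pixel size by $N$ (20 µm FT → 80 µm MS² at $N = 4$); y is set by
  the line step and is unchanged;
* schedule: row-major pixel traversal, pixel column $c$ (1-based) using
  list $(c-1) \bmod N$, one FT scan plus that list's windows per pixel, so
  any $N$ consecutive x positions cover every window exactly once.

The ion-trap scan time is not modelled; the number of MS² scans per FT
scan is a user input. Stage motion is modelled as a uniform pixel pitch —
continuous-line-scan effects (stage speed variation, oversampling) are out
of scope, and pixel registration assumes a regular grid with explicit
per-line record offsets (`line_breaks`) rather than retention-time
heuristics, keeping the mapping deterministic and testable.

## Reading runs and reconstructing images

`read_mzml()` (backed by mzR) returns centroided spectra in acquisition
order; profile data are rejected rather than centroided. MS² records carry
the isolation window center and width from the precursor element — their
absence is a hard error naming the spectrum, because window identity is
what routes a spectrum to its channel. `assign_pixels()` groups records
into per-filter channels on the grid; a pixel acquired under a filter but
lacking a peak scores 0, while a pixel never visited by that filter (e.g.
the trailing partial list cycle of an odd line) is masked invalid and
excluded from $P$. Extraction tolerances default to 0.3 Th for ion-trap
channels (unit resolution) and 5 ppm for FT channels.

`detect_product_ions()` supplies the per-window product-ion list when none
is given: it bins the valid-pixel mean spectrum (default 0.5 Th), keeps
bins above 1 % of the base bin that recur in at least 5 % of pixels, and
returns intensity-weighted centroids.

## Annotation and confidence

Clusters are matched against a delimited-text product-ion library (species,
neutral formula, adduct, diagnostic fragment m/z values). Precursor m/z
values are derived from the formula with monoisotopic element masses and
cationic adduct shifts that include the electron mass (+H = +1.007276 Da),
and are re-validated on library load. FT peaks inside the isolation window
are matched to library precursors within a ppm tolerance — 3 ppm by
default, which is what separating co-isolated isobars a few tenths of a
mDa apart near m/z 808 requires. Candidates per cluster are ranked by the
lexicographic key (fraction of diagnostic ions matched, fraction of
cluster explained, smaller |ppm|); exact ties are flagged, never broken
silently.

The five-level MSI annotation confidence scale is encoded in
`assign_confidence()`: Level 5 accurate mass only; Level 3 accurate mass
plus MS² from a few pixels; Level 2 fragmentation at all pixels plus
product-ion clustering above the similarity threshold plus a library
match; Level 1 adds confirmation against a reference standard with
orthogonal validation. Level 4 is deliberately never auto-assigned — the
rubric slot is exposed as a user-supplied function, because no generally
agreed criterion distinguishes it from Levels 3 and 5 in the main rubric.
Accurate mass is required for any level; the scale is anchored on it.

## The synthetic phantom generator

No public MS²I reference dataset accompanies this problem domain, so the
package ships a first-class generator that writes standard mzML
(`simulate_dataset()`, also mzR-backed) from a spatial phantom, a species
cast and a noise model, together with complete ground truth. It emulates:

* a pixel grid scanned line by line under a PIA schedule (one FT scan plus
  the pixel's inclusion-list windows per pixel, lists cycling along x);
* co-isolation: all species assigned to one window contribute their
  fragment peaks to that window's per-pixel MS² spectra, so spectra are
  chimeric wherever regions overlap;
* region-structured abundance maps (band / disk / full field / complement,
  optional linear gradients) standing in for tissue structures;
* shot noise (Poisson on expected counts), additive exponential baseline
  peaks, and per-pixel dropout of low-intensity fragments. "Low" is
  defined by an expected-intensity ceiling (`dropout_max_intensity`,
  default all fragments), since no quantitative noise characterization of
  such pixels exists to calibrate against — the noise parameters are
  knobs, not measured values.

The default demo cast mirrors the canonical co-isolation situation: three
PC species with precursors 808.5832 / 808.5856 / 808.5622 sharing the
0.7 Da window at m/z 808.6, on a band, a disk and the full field, with
fragment sets including the 465 / 467 / 469 acyl-chain markers. FT peaks
carry 5-decimal m/z so ppm matching is exercised; fragment peaks are exact
centroids. What the generator does *not* emulate — isotope envelopes,
charge states above 1, peak shape and resolution, matrix effects,
continuous-scan pixel blur — bounds what passing tests show: they validate
the algorithmic pipeline, not robustness to every instrumental artifact of
real tissue data.

## Numerical and design choices

* Default metric cosine with $\tau = 0.90$, always user-overridable; for
  SSE/MSE the edge rule is $\le \tau$ after per-image unit-maximum
  normalization, so thresholds are comparable across ions of different
  abundance. Both normalization and threshold are explicit in
  `metric_spec()` / `cluster_params()`.
* Degenerate (all-zero) images score 0 against everything, are flagged,
  and survive to the cluster set as singlets.
* Patch defaults $p = 4$, mean pooling; patches straddling the valid mask
  pool over their valid pixels only, and patches with none are masked.
* Pixel coordinates are 0-based in acquisition index, 1-based (row,
  column) in R matrices; row = scan line, column = position along the scan
  direction, row-major from the first acquired spectrum.
* Cross-dataset ion matching for Jaccard: greedy nearest-m/z within
  0.3 Th, each registry entry claimed at most once per dataset; unmatched
  ions enlarge the union.
* The Jaccard index is defined as 1 when all sets are empty; recovery is
  1 when no reference peak clears the relative-intensity floor.
* All generator randomness funnels through one seeded stream; a noise seed,
  when given, replaces the simulation seed so one phantom can be
  re-realized under independent noise draws with identical ground truth.

### Study conditions used by the checks

The property checks run at desk scale, chosen once: a 12 × 12 pixel
phantom (13-pixel disk, 36-pixel band), three co-isolated species at
abundances 1000 / 800 / 500 counts, clustering at the default
$\tau = 0.90$ over 20 generator seeds for exact-recovery, and two
independent noise realizations for the reproducibility check. "Moderate
noise" there means shot noise plus two baseline peaks per spectrum (mean
20 counts) — dropout is deliberately excluded from that definition because
it is this package's model of low-S/N *non-detection*: on a 13-pixel
region even a few per cent of dropout removes whole pixels and correctly
splits clusters at $\tau = 0.90$, a behaviour exercised by its own
degradation and singlet checks instead. The component-oracle check covers
all graphs up to 8 nodes over 200 random edge sets plus 100 random
15-node graphs against a brute-force transitive closure.

## Known limitations

* imzML and vendor raw formats are not read; mzML only, centroid only.
* Only connected components are offered for clustering — no community
  detection; the three stated metrics only.
* Adducts are restricted to +1 cations; isotope-pattern scoring and
  de novo fragmentation prediction are out of scope, and the shipped demo
  library is a synthetic fixture for the PC examples, not a curated
  reference.
* The uniform-grid registration assumption means continuous-line-scan
  distortions must be corrected upstream.
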