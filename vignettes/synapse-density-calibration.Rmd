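---
title: "Calibrating 2D puncta densities to 3D synapse densities"
author: "synapdens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating 2D puncta densities to 3D synapse densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapdens)
```

## The problem

Genetic labeling of the postsynaptic scaffolding proteins PSD95 and
SAP102 makes excitatory synapses visible as fluorescent puncta in
spinning-disk confocal (SDM) images, which can be acquired brain-wide.
But a punctum count is a 2D areal density (puncta per 100 µm²) of
labeled objects, not a volumetric density of actual synapses: puncta
can be clusters, small synapses are missed, and only marker-expressing
synapses are seen. Volume electron microscopy (FIB-SEM) gives the
ground-truth volumetric density (synapses/µm³) and the type of every
synapse — asymmetric (AS, excitatory, prominent postsynaptic density)
versus symmetric (SS, inhibitory, thin PSD) — but only over tiny
tissue volumes.

`synapdens` implements the analysis that joins the two: detect and
measure puncta in 2D; count and size synapses in 3D with unbiased
stereology; calibrate, per cortical/hippocampal layer, a conversion
factor

\[ k \;=\; \frac{\text{AS density (synapses/}\mu m^3)}
              {\text{total puncta density (puncta/100 }\mu m^2)} , \]

and extrapolate *minimum* volumetric synapse densities to any region
where only puncta densities are known. Because neither microscope can
be shipped inside a package, every stage has a synthetic generator
with exact ground truth, and the test suite treats the generators as
the experiment.

## The density algebra

Two channels double-count synapses that express both markers. With
per-channel densities $d_{PSD95}$, $d_{SAP102}$ and a colocalization
index $c \in [0, 1]$ (the fraction of punctum entities present in both
channels), the total density satisfies

\[ d_{Total} = d_{PSD95} + d_{SAP102} - d_{Coloc}, \qquad
   d_{Coloc} = c\, d_{Total}, \]

so $d_{Total} = (d_{PSD95} + d_{SAP102})/(1 + c)$. `total_density()`
implements this and enforces its invariants (symmetry in the two
channels, monotone decrease in $c$, $\max(d_1, d_2) \le d_{Total} \le
d_1 + d_2$).

```{r algebra}
total_density(91.3103, 77.1788, 0.5840)   # SLM-like layer means
conversion_factor(1.5958, 106.4372, "SLM")
```

The layer-averaged factor is the mean of the per-layer factors, each
computed from that layer's mean densities; a pooled alternative
(quotient of across-layer means) is available in
`averaged_conversion_factor()`. The mean-of-factors reading is the
default because it matches how a per-layer table with an "averaged"
row is constructed; the two differ in the fourth decimal.

Region estimates are always flagged `"minimum estimate"`: puncta only
see marker-expressing synapses, so $k \cdot d_{Total}$ bounds the true
excitatory density from below.

## The fluorescence side

**Detection.** Candidate puncta are local maxima of a multi-scale,
multi-orientation second-order nonlocal-derivative (NLD) response:
for scale $s$ and orientation $u$,
$f(x) = I(x) - \tfrac12\!\left[I(x+su) + I(x-su)\right]$, aggregated
as min-over-orientations (suppressing ridges) then max-over-scales.
The candidate threshold is deliberately near zero — recall first — and
a seeded random-forest classifier trained on labeled synthetic fields
removes background-noise candidates. The classifier is part of the
module surface, not of the science: any supervised learner meeting the
held-out ROC bound (AUC ≥ 0.95) is acceptable.

**Segmentation.** Each accepted punctum is segmented as the connected
component, containing its peak, of pixels at or above 10% of the
punctum's peak intensity. The rule is scale-free: multiplying the
image by any positive constant leaves masks unchanged. On a nonzero
background the rule is ill-posed, so the field median is subtracted
first (clamped at zero); the median is robust because puncta occupy a
small fraction of the field.

**Morphometry.** Six descriptors per punctum: mean pixel intensity;
size (pixel count × physical pixel area, 84 nm pixels → 7,056 nm²
each); skewness and non-excess kurtosis of within-mask intensities;
circularity $4\pi A / P^2$ with the perimeter from Moore boundary
tracing, Kulpa-corrected (×0.948) for the digital staircase and offset
by $\pi$ from the pixel-center path to the physical outline; and
aspect ratio from the intensity-weighted second-moment ellipse (with
the pixel's own 1/12 variance added, so single-row masks stay finite).

**Colocalization.** Object-based: puncta from the two channels are the
same entity iff their masks share a pixel (masks that merely touch
also pair when their detection peaks are within 2 px — near
diffraction-limit puncta can have one- or two-pixel masks). All
candidate pairs are gated by a peak distance of 2.5 px and assigned
one-to-one greedily by nearest peak: in dense fields, the 10% masks of
neighboring puncta merge, and peak positions remain reliable when
intensity centroids do not. The index is $c = n_{both}/n_{entities}$.
The centroid-distance definition (≤ 200 nm) is available as
`method = "centroid"`.

## The EM side

**Counting.** Synapse records carry full spatial extents; an unbiased
3D counting frame (brick) counts an object iff it intersects the frame
and touches none of the three exclusion faces. With the default
high-face exclusion this is exactly "the object's maximal corner lies
in the half-open frame", which gives each object a unique associated
point — the property that makes a tiling count every object once and a
randomly placed frame estimate density without bias. A
centroid-association rule is provided for cross-checks.

**Shrinkage.** EM processing shrinks tissue; `shrinkage_from_linear()`
derives area and volume factors as the square and cube of the linear
factor (0.9508 → 0.9040, 0.8595). The correction direction is: in-vivo
volume = measured volume ÷ volume factor, so densities scale *down* by
the factor. Published stack volumes are usually already corrected,
hence `volume_is_corrected = TRUE` by default; the direction is
recorded in every calibration report.

**SAS areas.** The synaptic apposition surface is the zero-volume
midsurface between the apposed faces of the presynaptic density and
the PSD; its area is the size of the synapse. Raw counting of voxel
faces overestimates tilted surfaces by up to the Manhattan factor
$|n_x| + |n_y| + |n_z|$ (≈ 37% at 30°), so `extract_sas()` uses a
local-orientation estimator: apposed faces are grouped into 40 nm
blocks, the face-area-weighted normal vectors are summed per block,
and the area is the sum of block vector magnitudes. For a digitized
plane the axis-aligned face areas are exactly the projections of the
true patch, so the estimate is exact up to rim effects; on spherical
caps the error is set by (block size / curvature radius)² — a few
percent at synaptic geometry. Voxel anisotropy (5 × 5 × 20 nm) is
honored throughout, and the apposition search range is physical
(40 nm ≈ two sections) rather than a fixed voxel count, which would
mean different distances along different axes.

**AS/SS classification.** In micrographs the call is "prominent vs
thin PSD relative to the presynaptic thickening". Here it is a
thickness-ratio rule: AS iff PSD plate thickness ≥ 1.5 × presynaptic
plate thickness (threshold configurable). Thickness is measured by
median chord counting along the axis most aligned with the SAS normal,
projected onto the normal, minus the voxel-support term $\sum_i |n_i|
d_i$ that rasterization adds to plates thinner than a voxel. Chords
cross the plate locally, so plate curvature does not bias the
estimate; a volume/area estimator was rejected because the radial
divergence of curved shells inflates the outer (PSD) plate and
deflates the inner one.

## The synthetic generators

`make_puncta_field()` renders two-channel 16-bit fields
(43.008 µm / 512 px at 84 nm by default). Entities are decomposed into
channel-1-only, channel-2-only and both-channel Poisson components
with rates $\lambda_1 - \lambda_b$, $\lambda_2 - \lambda_b$,
$\lambda_b = c(\lambda_1 + \lambda_2)/(1 + c)$ — so per-channel counts
are exactly Poisson with mean density × area while the colocalized
fraction converges to $c$, and the generative model obeys the same
algebra the analysis inverts. Each punctum is an anisotropic Gaussian
spot whose 10%-of-peak contour encloses exactly its ground-truth area
(drawn log-normal on the nm² scale, defaults µ = 11.21, σ = 0.46);
segmentation therefore has an analytic target. Spots sit on a constant
background with additive Gaussian noise. Placement is hard-core with
0.25 µm minimum separation — about a synapse diameter; a 1-pixel
hard core would let ~12% of puncta merge irrecoverably at realistic
densities, which no detector could undo. Peak amplitudes are uniform
on a configurable range: spot brightness distributions are not
constrained by the imaging model, so this is a free parameter.

`make_em_population()` / `make_em_volume()` generate synapses as
paired spherical-cap plates (PSD + presynaptic density) separated by a
20 nm cleft, with SAS areas log-normal per type (AS: µ = 10.54,
σ = 0.64; SS: µ = 10.70, σ = 0.69), isotropic orientations, mild
curvature (cap height / base radius = 0.25), and PSD thicknesses of
40 nm (AS) vs 20 nm (SS) against a 15 nm presynaptic plate — the
geometric encoding of "prominent vs thin". Rendering honors the
5 × 5 × 20 nm anisotropy; a voxel belongs to a plate when its support
interval along the local radial direction intersects the plate slab,
which keeps sub-voxel plates connected at any orientation. The
population path (records with bounding boxes, no voxels) makes
large-scale stereology experiments cheap.

What the generators do *not* emulate: optical PSF depth effects,
photobleaching, mosaic stitching seams, uneven illumination, EM
milling artifacts, membrane ultrastructure, perforated PSDs, or
spatial clustering of synapses beyond hard-core exclusion. Passing
tests therefore demonstrate that the *algorithms* are correct and
unbiased on a faithful geometric model of the data — not that the
pipeline is robust to every artifact of real microscopes.

## Statistics

Group comparisons follow a gate: Shapiro–Wilk normality per group and
Levene homoscedasticity (Brown–Forsythe median centering) at α = 0.05
choose between one-way ANOVA (with pooled-SD pairwise t tests) and
Kruskal–Wallis with Dunn's rank-based pairwise comparisons (exact
Mann–Whitney for two groups). Dunn's z statistics use the tie-corrected
variance and Holm adjustment by default; unadjusted values are
available for comparison with published pairwise statements. The gate
tests are the package's choice — the analysis convention names no
specific normality or variance test. The statistical unit is whatever
the input rows carry (sections, animals, stacks); the module does not
impose a hierarchy.

## Orchestration, seeds, and problem sizes

`run_calibration()` drives simulate → detect → count → calibrate for a
three-layer configuration whose defaults mirror hippocampal CA1
magnitudes (SLM/SR/SO-like). Every stochastic stage derives its seed
deterministically from the global seed and the stage name
(`derive_seed()`), so re-running a configuration is bit-identical;
reports carry the config hash, the seed and the shrinkage direction.
Synthetic calibrations default to `shrinkage_linear = 1` because
generated volumes are not shrunken tissue — applying a correction
would bias the recovered factor against its own ground truth.

Desk-scale sizes used by the test suite and the acceptance script are
package choices balancing statistical power against laptop runtimes:
21.5 µm (256 px) fields for calibration, 15.1 µm fields for the
density/colocalization sweeps, 8–14 µm boxes for EM populations, 300
random counting frames in a 1,728 µm³ population, 20,000 draws for
log-normal recovery, and ≥ 5,000 rendered synapses for the AS/SS
mixture check. Recovery is always judged against the *realized* ground
truth of each simulated field or volume, so finite-size Poisson
fluctuation does not masquerade as algorithmic error.

## Known limitations

- Colocalization is resolution-dependent by construction; the overlap
  definition is a documented choice, not a published convention, and
  the 2.5 px peak gate is tuned to the 84 nm pixel pitch.
- Optical-section thickness is not corrected for; puncta densities are
  areal by definition.
- AS/SS classification assumes the generator's plate-thickness
  contrast; on real segmentations the ratio threshold would need
  re-estimation against expert calls.
- The SAS estimator degrades for surfaces curved at scales near its
  40 nm block size, and chord-based thickness quantizes at the 20 nm
  section pitch for near-axial synapses (a ±2 pp mixture error is the
  tested envelope).
- Sequential hard-core placement slightly enriches density near volume
  boundaries at high packing; counting-frame margins of ≥ 0.5 µm keep
  the effect out of the tested frames.
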