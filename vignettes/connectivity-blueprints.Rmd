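---
title: "Connectivity blueprints and cross-brain divergence on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity blueprints and cross-brain divergence on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractoprint)
```

## The analysis this package implements

Comparative tractography asks how the long-range white-matter organization
of one brain relates to another. The workflow implemented here follows the
design used to compare temporal-lobe organization across primates:

1. **Connectivity-based parcellation.** Voxels of a white-matter region of
   interest (a slab of consecutive "coronal" slices) are each seeded with
   unconstrained probabilistic tractography. Two voxels belonging to the
   same fiber bundle have similar whole-brain visitation profiles, so the
   Pearson similarity matrix of these profiles, clustered with k-means,
   localizes the bodies of the bundles crossing the slab.
2. **Protocol-constrained tract reconstruction.** The clusters, assigned to
   bundles and aggregated across subjects into probability maps, yield
   equally sized, disjoint seed and waypoint masks. Streamlines are sent
   from the seed, retained only if they cross at least one waypoint,
   deleted on contact with exclusion masks, and stopped (but kept) at the
   gray-matter border. Visitation counts divided by the number of retained
   streamlines give a normalized tract map.
3. **Connectivity blueprints.** Multiplying a vertex-by-voxel connectivity
   matrix (tracking from the gray/white border into the volume) with a
   voxel-by-tract matrix of normalized tract maps yields the blueprint: one
   row per cortical vertex, one column per tract, each row normalized to a
   probability distribution — the vertex's connectivity fingerprint.
4. **Divergence.** Fingerprints live in a common tract space for both
   brains, so each vertex of one brain can be compared with every vertex of
   the other by Kullback–Leibler divergence,
   $\mathrm{KL}(p\|q) = \sum_i p_i \ln\frac{p_i + \varepsilon}{q_i + \varepsilon}$
   (natural log, $\varepsilon = 10^{-8}$; terms with $p_i = 0$ vanish). The
   per-vertex minimum over the other brain is low where a matching
   fingerprint exists and high where the vertex's connectivity is unique to
   its brain. Distributions of strictly positive minima are compared by the
   two-sample Kolmogorov–Smirnov test; differences between blueprint
   variants (e.g. swapping which subcomponent of a split bundle occupies
   the shared column) are read from per-vertex difference maps.

Real inputs to such an analysis are diffusion MRI volumes; this package
replaces them with synthetic fiber-orientation phantoms with known ground
truth, so that every stage is testable end to end on a desk.

## The phantom generator and what it emulates

`generatePhantom()` builds a voxel grid (default $40^3$ at 1 mm) whose
posterior end carries a gray-matter plate; the gray/white border is a
triangulated surface with one vertex per boundary face. Longitudinal
bundles are tubes (radius 2.5 voxels) around centerlines running toward the
plate. At each bundle voxel the stored orientation is the local centerline
tangent rotated by a folded-normal angle (sd `dispersionDeg`, default 10°)
about a uniformly random perpendicular axis — a simple isotropic stand-in
for a crossing-fiber posterior. Orientations are axial (no polarity) with
the sign convention "first nonzero component positive". Background white
matter is isotropic: the tracker draws a uniformly random direction there,
which makes off-tract propagation diffuse and short-lived rather than
forbidden.

The canonical layouts (`demoPhantomSpec()`) encode the qualitative
differences the comparison is designed to detect: `"three-straight"` has
three parallel bundles (MdLF-, IFOF- and ILF-analogues); `"split-ilf"`
splits the ILF-analogue into a lateral child (shifted 6 voxels) and a
medial child congruent with the unsplit parent; `"with-arcuate"` adds a
curved dorsal bundle absent from the other layouts, ending in its own
cortical territory. The tubes are deliberately adjacent (edge gaps of one
to a few voxels), as the temporal longitudinal tracts are: with angular
dispersion this produces partially overlapping visitation territories and
therefore *mixed* fingerprints near bundle borders. Without that adjacency
every fingerprint is an exact one-hot vector, all minimum divergences are
exactly zero, and distribution-level comparisons degenerate.

Cohorts (`generateCohort()`) displace all centerlines of each subject
rigidly in the cross-sectional plane by Gaussian jitter (default sd 1
voxel, clamped at 2.5 sd). A rigid displacement preserves the declared
bundle adjacency — independent per-tube jitter would make adjacent tubes
collide — while still moving cluster positions and bundle masks between
subjects, which is what the probability-map and averaging stages need to be
exercised. No quantitative inter-subject variability was available to
calibrate against; 1 voxel is of the order of the registration error such
studies tolerate. The phantoms emulate the *statistical* structure the
analysis assumes (multi-bundle orientation fields with dispersion, a
gray/white border, known vertex homology); they do not emulate
gyrification, crossing-fiber voxels within a tube, distance-dependent
signal loss, or realistic brain shapes, so passing tests show the method's
machinery is correct, not that it is robust to those real-data effects.

## The tracker and its conventions

Streamlines take Euler steps of `stepLength` (default 0.5 mm) along
directions sampled at the *containing voxel* (no interpolation, for both
orientation lookup and mask tests — the simplest convention that makes test
expectations exact on coarse grids). Propagation stops at the step cap
(default 2,000, never binding on these phantoms), on leaving the grid, on
entering the termination mask, or when the cosine between successive
directions falls below the curvature threshold (default 0.2). Exclusion
masks are tested on every visited voxel including the seed. Retention
requires crossing at least one waypoint (OR logic). Each retained
streamline increments a voxel at most once, so the normalized map is the
probability that a retained streamline visits the voxel. Seeds launch half
their samples with each initial axial sign, reproducing a middle-seed /
two-waypoint design.

Randomness is organized for exact replay: a master generator seeded with
`params@seed` draws one substream seed per streamline; each streamline then
consumes three uniforms for its start offset and exactly three per step
(selection, angle, axis), regardless of voxel type. This fixed-width
protocol lets a plain scalar reimplementation in the test suite replay the
identical stream and match every retention decision bit for bit, and it
makes results independent of batch size. Deterministic mode (the
comparator for the probabilistic/deterministic agreement analyses) uses no
randomness at all: one streamline per initial sign from each seed voxel
center, always following the highest-weight orientation — hence its output
is invariant across seeds by construction.

## Numerical and design choices

* **Similarity** is the Pearson correlation of connectivity rows (unit
  diagonal, exact symmetry enforced; zero-variance rows get similarity 0).
  Correlation rather than raw dot products keeps voxels with different
  seeding efficiency comparable.
* **k-means** runs on the rows of the similarity matrix with 50 seeded
  random restarts (`stats::kmeans`; no k-means++ implementation is used —
  on these small, well-separated similarity matrices multi-restart k-means
  reaches the same optimum deterministically under a fixed seed). Clusters
  are relabeled canonically by descending size, ties by lowest voxel index.
* **Cluster-to-tract assignment** maximizes total overlap with the
  reference label volume via the Hungarian algorithm (ties to the lowest
  tract id; zero-overlap clusters stay unassigned). On real data this step
  is anatomical; the phantom's ground-truth labels take that role.
* **Hierarchy index**: each (k+1)-cluster's parent is the k-cluster with
  maximal overlap; the index is the fraction of voxels contained in their
  parent. The reference describing the original index was not available,
  so this containment form is a documented reconstruction, validated by
  its fixed points (1 for perfect refinements, chance level under label
  permutation).
* **Mask derivation** takes the `nVoxels` highest-probability voxels per
  tract and position; conflicts go to the tract with the higher probability
  (then lower tract id), losers take their next-best voxel, so the masks
  are equally sized and disjoint by construction.
* **Blueprint rows are normalized to sum 1** before any masking. The
  divergence is only defined between probability distributions, and
  normalizing before masking keeps a vertex's fingerprint independent of
  which lobe mask is applied later (the alternative — normalizing after
  masking — would re-weight fingerprints by the mask). All-zero rows are
  flagged and excluded from matching pools in both directions.
* **KL regularization** uses natural log and a symmetric
  $\varepsilon = 10^{-8}$; the tiny negative values this can produce at
  near-identical fingerprints (order $10^{-7}$) are clipped to zero.
  Minimum-divergence ties break to the lowest vertex id.
* **Surface smoothing** is iterative symmetric edge diffusion
  ($\lambda = 0.125$) run for the number of iterations whose accumulated
  variance matches a Gaussian of sd = FWHM/2.3548; it preserves constants
  and total mass exactly and leaves isolated vertices unchanged.
* **Tract territories** on the surface are vertices whose smoothed,
  log-normalized (`log(1+v)/max`) projection exceeds the display threshold
  (0.7 by default, 0.5 where a more inclusive territory is wanted); for
  ground-truth territories the bundle's labeled voxels are projected along
  the tracking axis and dilated (`bundleFootprint()`).

## Problem sizes used in tests and the acceptance script

Parcellation analyses run on $40^3$ grids with 500 streamlines per ROI
voxel and 4-subject cohorts; blueprint and divergence analyses use 100
streamlines per surface vertex and per tract seed voxel. These sizes were
chosen so that sampling noise in the fingerprints sits well below the 0.05
nat identity threshold while a full two-species comparison completes in
minutes on one CPU; doubling the sampling changes the reported fractions
only in the third decimal.

## Known limitations

* The gray/white border is a flat plate; there is no gyral geometry, so
  gyral-bias effects of surface-seeded tractography are not represented.
* One orientation per voxel: crossing-fiber voxels (the reason for
  multi-orientation posteriors in real pipelines) never occur, although the
  container and sampler support several weighted orientations per voxel.
* The deterministic comparator shares the phantom's orientation model; it
  stands in for an alternative tracking algorithm only at the level of
  "independent technique, same protocol".
* Divergence values are reported in nats of the regularized KL; their
  absolute scale depends on $\varepsilon$ for fingerprints containing
  exact zeros (a tract absent from one brain saturates near
  $\ln(1/\varepsilon) \approx 18.4$).
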