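---
title: "Template-free hub mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-free hub mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hubtopo)
```

## The analysis

`hubtopo` maps structural hubs of a brain network without committing to any
anatomical parcellation template. The pipeline is:

1. **Nodes.** Each subject's grey-matter mask is partitioned `P` times into
   `K` regions of interest (ROIs) per hemisphere by randomly initialized
   k-means on voxel coordinates. Each run defines a different node set; the
   ensemble washes out the arbitrariness of any single node placement.
2. **Edges.** Streamline endpoints are mapped to ROIs; the number of
   streamlines joining two ROIs is the edge strength. Matrices are binarized
   without a strength threshold (an edge exists wherever at least one
   streamline connects the pair).
3. **Node metrics.** Node degree (local importance) and betweenness
   centrality (fraction of all-pairs shortest paths through the node,
   normalized by `2/((N-1)(N-2))`, endpoints excluded) are computed on every
   binary graph.
4. **Topographic maps.** Each voxel receives the average metric of the `P`
   ROIs it fell within; subject maps are smoothed with a 10 mm FWHM
   mask-renormalized Gaussian and averaged across subjects.
5. **Hub regions and scores.** Voxels strictly above the 80th percentile of
   the group betweenness map form the hub mask. Watershed flooding seeded at
   local maxima splits the mask at the saddles between peaks; a subject's
   hub score for a region is the maximum of their smoothed map over the
   region. Degree is scored on the same (betweenness-defined) regions.
6. **Statistics.** Bilateral region pairs are compared across hemispheres
   (pooled two-sample t, Bonferroni over pairs); sexes are compared per
   region (pooled t, Benjamini-Hochberg at q = 0.05 across regions) and via
   exact binomial tests on direction counts (Bonferroni n = 2, one family
   per metric); small-world indices `sigma = (C/C_rand)/(gamma/gamma_rand)`
   are computed per hemisphere against degree-preserving null networks, and
   compared by sex with and without adjustment for brain volume (OLS
   ANCOVA, sex as a two-level factor, no interaction).

All subjects of a synthetic cohort share one voxel grid, so group averaging
needs no registration step: the shared grid plays the role of a common
anatomical space, and this identity registration is the principal
representational departure from surface-based processing of real cohorts.

## The synthetic cohort generator

No public data exist for this design, so the package ships a generator that
plants the structure the analysis is meant to detect. A two-lobed
mirror-symmetric ellipsoidal mask defines grey matter and hemispheres.
Ground truth consists of bilateral zone pairs (default 18, matching the
number of hub regions the analysis is designed to recover), placed in the
left hemisphere by maximin farthest-point sampling, mirrored, and jittered
by up to one voxel per axis.

Streamlines are i.i.d. draws of unordered voxel pairs from a three-component
mixture:

* **background** — rate `exp(-d / lambda)` with `lambda = 6` mm, giving the
  short-range, lattice-like connectivity of cortex. Pairs straddling the
  midline are penalized by a factor of 0.05: interhemispheric background
  wiring is kept sparse (callosal connections are far rarer than short
  association fibres), so long-range interhemispheric traffic must route
  through connector bridges — which is precisely what makes connector zones
  betweenness hubs. An optional smooth lognormal gain field
  (`heterogeneity_sd`) can modulate the background regionally; it is off by
  default (see the limitations section for why).
* **provincial** (10% of mass) — dense wiring within provincial zones,
  producing high degree without high betweenness.
* **bridge** (15% of mass) — endpoint pairs linking every pair of connector
  zones. Zone kernels are Gaussians (`sigma = radius/2`) normalized to unit
  mass so boundary-cropped zones receive the same fibre budget; a
  lateralized zone's kernel is then scaled by `1 + 0.3`, planting a
  hemispheric asymmetry.

Sex effects mirror the group differences the statistics must recover:
female subjects have their bridge rate multiplied by 1.5 (raising connector
betweenness), male subjects have their total streamline count multiplied by
1.2 (raising degree everywhere), and female brain volume is drawn with a
10% lower mean. The effect sizes are calibration choices — the reference
results report only directions and significance counts, not hub-level
effect magnitudes — chosen so the planted directions are recoverable at the
package's validation scales while the null (all effects off) stays
calibrated.

The streamline budget is calibrated so that binarized connectomes realize
about 9.77% of possible connections, the density the analysis was designed
around: 81,000 draws at the default scale (32x38x32 grid, K = 500) and
2,700 at the medium validation scale (20x24x20 grid, K = 100). Degree
distributions come out right-skewed, as they should for single-scale
small-world networks.

### What the generator does not emulate

Real anatomy (folding, surface topology), tractography error structure
(false continuations, gyral bias, distance-dependent seeding artifacts),
inter-subject anatomical variability and registration error, and — by
default — regionally heterogeneous background connectivity. Passing the
recovery experiments therefore shows that the pipeline's inference
machinery is sound — not that it is robust to the failure modes of real
diffusion data.

## Validation scales

The full default configuration (63 subjects, K = 500, P = 20) reproduces
the reference settings but is needlessly large for testing the machinery.
The suite runs three frozen scales (`demo_config()`):

| scale  | grid      | K   | P | cohort | streamlines | used for |
|--------|-----------|-----|---|--------|-------------|----------|
| tiny   | 16^3      | 30  | 3 | 3F/3M  | 2,500       | smoke tests, IO, resume |
| small  | 16x20x16  | 40  | 2 | 6F/4M  | 400         | repeated-cohort experiments (direction recovery, null calibration) |
| medium | 20x24x20  | 100 | 5 | 7F/5M  | 2,700       | planted-hub recovery, acceptance script |

The medium scale keeps the density target (streamline budget calibrated to
9.77%); the small scale trades density realism for the ability to run tens
of cohorts in a test.

## Numerical and design choices

**k-means variant.** Lloyd's algorithm with k-means++-style seeding from the
voxel set, at most 300 iterations, convergence when assignments stop
changing. Empty clusters are re-seeded at the voxel farthest from its
current centroid, so exactly `K` non-empty ROIs always result (the
partition invariant downstream stages rely on). Spatial contiguity of ROIs
is reported (26-connectivity), not enforced: coordinate k-means does not
guarantee it, and silent relabelling would hide the violation.

**Betweenness convention.** Brandes' algorithm on the unweighted graph,
endpoints excluded, normalized by `2/((N-1)(N-2))`; this is the convention
under which a group-mean betweenness of order 1e-3 arises for
thousand-node cortical graphs. For `N < 3` the normalization is undefined
and zeros are returned with a warning.

**Disconnected graphs.** All path-based quantities are computed on the
largest connected component, with the component fraction reported;
silently averaging infinite distances is never acceptable.

**Null model.** Maslov-Sneppen double-edge swaps (10 attempts per edge)
preserving every degree exactly; an Erdős–Rényi alternative with matched
node and edge counts is exposed (`null_model = "erdos_renyi"`) because the
literature is not unanimous about what an "equivalent random network"
means, plus an identity null as a self-consistency hook (`sigma = 1`
exactly). `n_null` defaults to 10.

**Percentile and watershed.** The hub threshold is the linear-interpolation
quantile (R type 7) of in-mask voxel values; "in the 80th percentile" is
read as strictly above that value (the top 20%). Manual separation of
merged hub regions at inflection lines is automated as descending-value
watershed flooding seeded at 26-connected local maxima; regions smaller
than 5 voxels are merged into their strongest neighbour.

**Stage order for scores.** Subject hub scores are read from smoothed
subject maps (average over parcellations, then smooth, then score), so a
subject's score and the group map that defined the region live on the same
smoothness scale.

**Per-subject parcellation ensembles.** Each subject is parcelled
independently (`P` ensembles per subject, seeds derived from the master
seed). Sharing one ensemble across subjects would plant identical
node-placement noise in every subject's map; that shared geometry would
then masquerade as a group effect, because between-subject variance cannot
see it.

**Symmetrized hemispheric scoring.** For left-vs-right score comparisons,
each bilateral pair is replaced by the union of the left member and the
mirrored right member (and its mirror image), so both scores are maxima
over anatomically corresponding voxel sets. Without this, shape differences
between the two members — shared by all subjects — bias the paired
comparison arbitrarily; with it, a mirror-symmetric cohort gives calibrated
type-I error. Sex comparisons use the original (unsymmetrized) regions,
since both groups share whatever geometry a region has.

**Hemisphere comparison design.** The natural design for left-vs-right is
paired (each subject contributes both hemispheres); the pooled two-sample
design (df = 2n - 2) is reported alongside and flagged primary, matching
the degrees-of-freedom convention of the reference analysis. Both are
returned; readers can use either.

**Hemispheric subgraphs.** Induced subgraphs on one hemisphere's nodes:
inter-hemispheric edges are dropped.

**Configuration hygiene.** All settings live in one validated configuration
(YAML round-trip, unknown keys rejected); every output directory embeds the
effective configuration and a checksum manifest, and all randomness derives
from the single master seed, so a run is reproducible byte for byte.

## Known limitations

* Volumetric analysis on a shared synthetic grid; no surface projection or
  template registration, so spatial claims about real cortices are out of
  scope.
* The homogeneous background couples ROI degree mildly to ROI volume
  (pooled size-degree correlation around 0.37, so cluster size explains
  roughly 14% of degree variance — weak, but larger than in real cortical
  data, whose regional heterogeneity decorrelates the two). The
  `heterogeneity_sd` gain field can emulate that heterogeneity, but at the
  reduced validation scales any strength that materially lowers the
  correlation also creates spurious betweenness peaks that compete with the
  planted zones, so it ships disabled; the suite asserts the achieved
  property (size explains < 25% of degree variance).
* Hemispheric max-score comparisons have limited power at the validation
  cohort sizes: a planted one-zone rate asymmetry shifts betweenness
  scores non-monotonically (extra parallel bridges can reroute shortest
  paths), so the lateralization checks are run on the degree score, where
  the planted rate boost acts directly.
* Streamlines are reduced to endpoint pairs; fibre geometry, length and
  microstructure weighting are not modelled.
* The watershed substitute for manual peak separation has one tunable
  (minimum region size) and can split or merge differently than an
  anatomist would near shallow saddles.
* Exact binomial direction tests treat regions as independent; spatially
  correlated regions make them anti-conservative, which is one reason the
  direction counts are interpreted jointly with the per-region tests.
* At the validation scales, networks have 60-200 nodes; absolute metric
  values (e.g. mean betweenness) are not comparable with thousand-node
  cortical graphs, which is why recovery criteria are cast in scale-free
  terms (densities, directions, Dice overlaps, sigma ratios).
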