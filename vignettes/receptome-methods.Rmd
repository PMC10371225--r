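---
title: "Methods: receptome construction, gradients, nulls, and communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptome construction, gradients, nulls, and communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptome)
```

## The model

The package analyses *chemoarchitectural similarity*: every brain region is
described by its receptor fingerprint, the vector of neurotransmitter
receptor and transporter (NTRM) densities measured there, and two regions
are similar when their fingerprints rank the molecules alike. Concretely,
with a z-scored region-by-molecule density panel $X$ (one column per
molecule, z-scored per molecule over its compartment), the receptome is

$$R_{ij} = \rho_s(X_{i\cdot}, X_{j\cdot}),$$

the Spearman rank correlation (average ranks for ties) between the
fingerprints of regions $i$ and $j$. The same matrix container hosts
functional (FC), structural (SC), and microstructural-profile-covariance
(MPC) matrices for coupling analyses.

### Gradients

The main organizational axes of the receptome are extracted by
diffusion-map embedding:

1. each row is sparsified at its 90th percentile (top 10% of entries kept
   with their signed values, diagonal excluded and zeroed);
2. row profiles are converted to a nonnegative affinity with the
   normalized-angle kernel $a_{ij} = 1 - \arccos(\cos(x_i, x_j))/\pi$,
   which maps parallel, orthogonal, and anti-parallel profiles to 1, 0.5,
   and 0;
3. the affinity is anisotropically normalized,
   $W'_{ij} = W_{ij}/(d_i^\alpha d_j^\alpha)$ with $\alpha = 0.5$ (retaining
   global relations while damping sampling-density effects), row-normalized
   to a Markov operator, and eigendecomposed through its symmetric
   conjugate. The trivial constant eigenvector is dropped and components
   are scaled by $\lambda/(1-\lambda)$ (the diffusion-time-0 convention).

A component's *relative variance* is its share of the retained scaled
eigenvalue mass, $\lambda_i / \sum_j \lambda_j$ over the kept non-trivial
components. This definition matters for any comparison of variance
percentages and is therefore stated here explicitly. Component signs are
arbitrary in the eigenproblem; they are fixed so the node with the largest
absolute value is positive. Hemisphere-wise gradient sets (used for SC,
whose interhemispheric edges are unreliable) are aligned with an orthogonal
Procrustes transform (rotation/reflection, no scaling) before
concatenation. Rectangular (e.g. subcortico-cortical) similarity matrices
are embedded over their row profiles, and column values obtained by an
affinity-weighted projection of the row components.

### Spatial nulls

Parcellated brain maps are spatially autocorrelated, so correlating two of
them and consulting a naive permutation null inflates false positives (the
package's calibration tests measure roughly a fivefold inflation at
$\alpha = 0.05$ on smooth map pairs). Two surrogate generators preserve the
autocorrelation:

* **Variogram matching (VGM).** Each surrogate permutes the map, smooths
  the permutation with a truncated-Gaussian k-nearest-neighbour kernel over
  a candidate grid $k \in \{3, 5, 10, 20, \dots\}$ (capped at $n/4$), and
  fits $\gamma_{obs} \approx \beta\,\gamma_{smooth} + \alpha_{nugget}$ by
  least squares on the binned empirical variogram, selecting the $k$ with
  the smallest residual. The surrogate is
  $\sqrt{\beta}\,\text{smoothed} + \sqrt{\alpha_{nugget}}\,z$ with $z$
  resampled from the standardized original values, recentred to the
  original mean. The variogram is computed over pair distances up to their
  25th percentile (25 equal-width bins): autocorrelation is a short-range
  property, and fitting the flat sill would dominate the residual while
  carrying no spatial structure. All constants are arguments.
* **Spin permutation.** For unit-sphere geometries, a uniform random
  rotation (drawn via unit quaternions) is applied to left-hemisphere
  coordinates and its midline reflection to the right, and parcel values
  are reassigned by a bijective nearest-available match (conflicts won by
  the closer parcel, ties by lowest index). Each surrogate is therefore an
  exact permutation of the original values - the value multiset is
  conserved - while the spatial arrangement is randomized. Assignments
  touching the medial wall are marked discarded and dropped pairwise in
  downstream tests. Volumetric geometries must use VGM; a spin is undefined
  off the sphere.

Association tests report $\rho_s(x, y)$ with the two-sided
surrogate p-value $(1 + \#\{|\rho_{null}| \ge |\rho|\})/(n_{null}+1)$.

### Communities

Signed similarity matrices are clustered with a native Leiden-style
optimizer of the negative-asymmetric signed modularity

$$Q^* = Q^+ - \frac{v^-}{v^+ + v^-} Q^-,$$

where $Q^\pm$ are resolution-$\gamma$ modularities of the positive and
negative sub-networks and $v^\pm$ their total weights: positive weight is
concentrated within communities, negative weight pushed between them, with
the negative term down-weighted by its share of total weight. The
null-model term $k_i k_j / v$ sums over all pairs including $i = j$ (the
standard modularity convention; with this convention a single community at
$\gamma = 1$ on an all-positive uniform matrix scores exactly 0), while
observed weights exclude the matrix diagonal. $\gamma$ scales the null
term of both sub-networks. The optimizer runs local moving over seeded
random node orders, a refinement pass that rebuilds each community from
singletons with moves confined to the parent community, and aggregation,
until the quality stops improving; quality never decreases across phases
and results are bit-reproducible under a fixed seed.

Partition ensembles sample a resolution grid (defaults: cortical
$\gamma \in [0.5, 10]$ in steps of 0.05, i.e. 191 values with 1000 runs
each; subcortical $[1, 10]$ in steps of 0.5, 19 values with 250 runs) and
select per resolution the run with the highest mean z-rand score against
all other runs - the z-scored pair-counting Rand statistic under the
hypergeometric permutation null with the published analytic variance. A
high mean z-rand with low variance marks a stable partition; ties are
broken by lowest run index.

The **modular stability score** of a region of interest is
$C_{max}\,(1 - C_{in}/C_{tot})\,s$: the largest fraction of the ROI covered
by one community, discounted by the share of all communities that intrude
into the ROI, scaled by the ROI's relative size $s$. The printed source
formula omits its middle operator; the subtraction is the only reading
under which an ROI that does not fracture as resolution increases keeps a
high score, and it is the default here. Because the score is also
described as "normalized by" ROI size, a divide-by-$s$ variant is exposed
behind the `normalization` argument. The score is invariant to community
relabelling.

Hierarchical fingerprint clustering uses Euclidean distances with the
WPGMA update $d(k, i \cup j) = (d(k,i)+d(k,j))/2$
(`stats::hclust(method = "mcquitty")`).

### Consensus connectivity and coupling

* FC: subject matrices pass through Fisher's r-to-z (`atanh`) and are
  averaged; the consensus stays on the z scale by default since every
  downstream use is rank-based (a `back_transform` flag returns
  correlations).
* SC: subject matrices are `log(1+w)`-transformed (the `+1` handles the
  zeros of sparse streamline counts) and averaged; the consensus support is
  selected by distance-binned consistency thresholding - bin quotas follow
  the pooled subject edge-length distribution (largest-remainder allocation
  of the mean subject edge count) and each bin keeps its most consistent
  edges. This corrects the short-edge over-representation that plain
  averaging produces; the consensus edge count matches the mean subject
  count to within integer rounding per bin.
* MPC: depth-wise intensity profiles are partially correlated controlling
  for the grand-mean profile (residualize on the mean profile, correlate
  residuals); negative partials are clipped to zero and mapped through
  $\log((1+r)/(1-r))$. The source pipeline states only a log transform;
  any monotone log variant is equivalent for the rank-based coupling
  downstream, and the exact form used is recorded here.

Row-wise coupling between the receptome and another modality is the
Spearman correlation of the two matching rows over indices where both are
nonzero (diagonal excluded; rows with fewer than 3 shared entries return
`NA` with a warning). Coupling differences across cytoarchitectural
classes use the tie-corrected Kruskal-Wallis test with Dunn's post hoc
pairwise comparisons (large-sample normal approximation, tie-corrected,
Bonferroni-adjusted).

## The synthetic-data generator

All tests run on synthetic inputs that reproduce the statistical structure
the analysis assumes:

* parcel geometries as Fibonacci lattices on the unit sphere (seeded
  rotation, hemispheres split at $x = 0$, great-circle distances, optional
  medial-wall fraction nearest the midline);
* spatially autocorrelated maps drawn from a Gaussian field with
  exponential covariance $\exp(-d/\ell)$ (Cholesky with escalating jitter);
  the exponential kernel is heavy-tailed enough to stress the variogram
  fit;
* density panels $X = A L^\top + E$ with $k$ planted axes (centred
  Gram-Schmidt-orthogonalized smooth fields, unit sd, $\ell = 0.5$),
  loadings $L \sim N(0,1)$, and i.i.d. noise of sd `noise_sd`;
* signed block matrices (within-block $+0.8$, between-block $-0.4$,
  noise sd 0.05 by default) with the planted partition returned;
* subject stacks: FC as tanh of noisy distance-decaying z-templates; SC
  with Bernoulli$(e^{-d/\ell_{edge}})$ edge masks and lognormal weights
  (so naive consensus over-represents short edges, which the binned
  consensus must correct); MPC as noisy smooth log-scale templates;
* paired matrices with class-wise planted row coupling, mixing a
  rank-preserving copy of the reference row with noise at a per-class
  blend chosen from the target Spearman coupling.

What the generator does **not** emulate: PET tracer kinetics,
partial-volume effects, cortical folding, realistic receptor density
marginals, or subject-level covariance structure. Passing tests show the
pipeline recovers planted structure under idealized smooth-field
assumptions; they do not certify behaviour on real tracer maps.

### A known ceiling of single-axis recovery

With a single planted axis and weak molecule-specific variance, the
z-scored panel columns approach $\mathrm{sign}(L_m) \cdot a$ as noise
vanishes, so the rank-based fingerprint similarity saturates to a two-block
$\pm 1$ sign structure: every same-sign region pair is maximally similar
and the ordering *within* a block becomes invisible to any embedding of
the similarity matrix. The Spearman correlation between a sign indicator
and the underlying axis is $\sqrt{3}/2 \approx 0.866$, which therefore
bounds recovery in the low-noise regime; moderate unique variance
de-saturates the fingerprints and recovery improves with noise up to a
point. This is a property of rank-based similarity of one-dimensional
panels, not of the optimizer or the embedding; multi-axis panels (the
realistic case) do not saturate this way.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold_pct` | 90 | per-row sparsification percentile before the kernel (keep top 10%) |
| `alpha` | 0.5 | diffusion anisotropy; 0 = none, 1 = full density removal |
| `n_components` | 10 | retained non-trivial components (the relative-variance denominator) |
| `n_null` | 1000 | surrogates per ensemble; p-values floor at $1/(n_{null}+1)$ |
| `gamma` grids | 0.5-10 / 0.05 and 1-10 / 0.5 | cortical and subcortical clustering resolutions |
| `length_scale` | 0.5 | field correlation length (radians) of synthetic maps |
| `vario_quantile` | 0.25 | distance quantile bounding the fitted variogram |
| `n_bins` | 25 (VGM), 10 (SC) | variogram / edge-length bins |

## Numerical choices

* Percentile thresholding uses quantile type 7; ties at the threshold are
  all kept. Z-scoring uses the sample standard deviation (ddof = 1).
* The affinity cosine is clipped to $[-1, 1]$ before `acos`; eigenvalues
  are clipped just below 1 before the $\lambda/(1-\lambda)$ scaling
  (a connectivity check rejects the degenerate multiple-eigenvalue-1 case
  first, listing unreachable nodes).
* Covariance Cholesky factors get escalating diagonal jitter
  ($0, 10^{-10}, \dots, 10^{-4}$) before a positive-definiteness failure
  is raised.
* Leiden move gains use a $10^{-12}$ improvement tolerance; community
  ties resolve to the first (lowest-id) candidate. Per-run seeds derive
  from the master seed by a fixed affine map below $2^{31}$.
* Spin conflicts resolve to the closer parcel, then the lower index, making
  every surrogate deterministic given its rotation.
* Degenerate inputs error early and name the offender: constant
  fingerprints, zero-variance molecules within a z-scoring scope, all-zero
  rows after thresholding, profiles equal to the mean profile,
  $|r| \ge 1$ off-diagonal FC entries.

## Problem sizes used by the test-suite and acceptance script

The packaged checks run on 100-parcel spheres with 19 molecules (the
reference panel size), 60-node block matrices, stacks of up to 20
subjects, 200-500 calibration repeats with 100-200 surrogates per test,
and 10-50 seeds per recovery experiment; clustering ensembles in tests
sample small resolution grids with 4-10 runs per resolution. These sizes
were chosen so every statistical property is measured with useful
resolution at interactive runtimes; all of them scale up through function
arguments.

## Known limitations

* The relative-variance significance test discriminates planted structure
  from molecule-randomized panels only when eigenvalue mass concentrates
  (few axes); panels whose fingerprint similarity saturates spread mass
  across components and the test loses power.
* The spin generator requires near-uniform spherical parcel layouts; very
  uneven parcel sizes would need area weighting, which is not implemented.
* `run_pipeline()` executes the synthetic study end to end; real-data runs
  assemble panels from parcellated volumes with `parcellate_volume()` /
  `assemble_panel()` and call the stage functions directly.
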