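---
title: "Morphometric similarity networks: models, parameters and design choices"
author: "neomsn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomsn)
```

## The scientific problem

Structural covariance treats the similarity of two cortical regions'
anatomy as a proxy for their coordinated maturation or connectivity. A
morphometric similarity network (MSN) extends the classical
single-feature structural covariance network (SCN) by describing each
region with a multi-feature profile — here eight features typical of
perinatal imaging: cortical thickness (CT), mean curvature (MC), a
T1w/T2w myelin index (MI), pial surface area (SA), and the diffusion
metrics FA, MD, NDI and ODI — and defining the edge between regions
$i$ and $j$ within a single subject as the Pearson correlation of their
profiles:

$$\mathrm{MSN}_{ij}^{(s)} = r\!\left(z^{(s)}_{i\cdot},\; z^{(s)}_{j\cdot}\right),$$

where $z^{(s)}_{i\cdot}$ is subject $s$'s feature vector at parcel $i$
after each feature has been z-scored across the cortex (mean 0, sample
SD 1 over parcels, $n-1$ denominator). The z-score puts features with
different units on a common scale; it also makes the pipeline invariant
to positive rescaling of any raw feature, which the test suite checks
as a property. The group network is the element-wise mean of the
per-subject matrices. Because every subject contributes a full network,
individual variability and covariate effects (age, sex) can be studied
at the edge, node and module level — something a cross-subject SCN
cannot do.

The classical SCN is retained as a comparison construct: one feature,
edges defined by correlating two parcels' raw values across subjects.

## Clustering model

Modules are discovered with affinity propagation (AP): message passing
on the similarity matrix itself, with no thresholding or binarisation,
and no pre-specified cluster count. Responsibilities and availabilities

$$r(i,k) \leftarrow s(i,k) - \max_{k' \neq k}\left[a(i,k') + s(i,k')\right],
\qquad
a(i,k) \leftarrow \min\!\left(0,\; r(k,k) + \textstyle\sum_{i' \notin \{i,k\}} \max(0, r(i',k))\right)$$

are damped ($\lambda = 0.9$ by default) and iterated until the exemplar
set — the points with $r(k,k)+a(k,k) > 0$ — is stable for 100
consecutive iterations (budget 1000). The shared *preference* placed on
the diagonal controls how many exemplars emerge; following standard
practice we default to the median of the off-diagonal similarities,
which treats every parcel as an equally plausible exemplar. The
diagonal itself is excluded from that median because the preference
overwrites it. After convergence a refinement pass re-selects each
cluster's best exemplar and reassigns points until stable, as in the
reference implementation; on small well-separated instances the result
then matches exhaustive exemplar-set enumeration (verified on 100
random instances at $n \le 10$).

Two practical devices are documented rather than hidden:

* a seeded symmetric jitter of magnitude $10^{-12}$ breaks degenerate
  ties so runs are reproducible bit-for-bit;
* non-convergence is reported (`converged = FALSE`) with a warning, not
  an error, since long message plateaus are expected on near-degenerate
  matrices.

**Fixed cluster counts.** When a solution with exactly $k$ clusters is
needed (e.g. $k = 7$ to match a seven-class reference atlas), the
preference is found by bisection, exploiting that the achieved number
of exemplars is non-decreasing in the preference. The nominal search
bracket `[min(s) - range(s), max(s)]` is widened geometrically first
when the target lies outside it — merging genuinely separated blocks
into one cluster can require preferences far below the nominal lower
end.

## Partition comparison

Variation of information, $VI = H(P) + H(Q) - 2I(P,Q)$ in bits, is a
metric on partitions; its normalized form divides by the joint entropy
$H(P,Q)$, giving a dissimilarity in $[0,1]$ (0 iff the partitions agree
up to relabelling; defined as 0 when both partitions are trivial). The
joint-entropy normalization was chosen because it is the variant that
yields a $[0,1]$ range and matches the magnitudes such analyses report.
Dice tables ($2|A\cap B|/(|A|+|B|)$ per cluster/class pair) give the
interpretable per-pair overlap picture.

**Spin test.** Whether a clustering corresponds to a reference
labelling beyond chance is assessed with spatial permutations of the
spherical representation: each of `n_perm` (default 500) draws a
uniform random rotation (unit-quaternion sampling), carries the
reference labels through a nearest-centroid mapping, and records the
NVI against the clustering; the p-value is
$(1 + \#\{\mathrm{null} \le \mathrm{obs}\})/(1 + n_{perm})$ (add-one
convention, so p is never zero). Three properties of this design are
worth knowing:

* the nearest-centroid carrying is many-to-one, so a rotated map's
  label counts deviate slightly from the original's (the deviation is
  recorded per permutation; its mean is a few percent of parcels at
  150 parcels);
* that slight fragmentation of the null maps almost exactly offsets the
  advantage two unrotated maps gain from sharing the same parcel
  tessellation; empirically the test's rejection rate under
  independent contiguous label maps sits at the nominal level's upper
  95% binomial band (a mild residual anticonservatism of a few
  percent). Exact-rotation variants we evaluated (dense spherical
  resampling, bijective assignment) remove the fragmentation but not
  the shared-tessellation term and are substantially *more*
  anticonservative; they were rejected.
* two maps that are both mirror-symmetric about the same
  interhemispheric plane share genuine spatial structure; the test
  correctly flags such pairs as corresponding. Calibration must
  therefore be assessed with maps that share nothing but their spatial
  scale.

## Association statistics

All covariate analyses are nonparametric, since scan age need not be
normally distributed: Spearman's $\rho$ (Pearson on mid-ranks, p from
the $t$ approximation with $n-2$ df) for age, Mann-Whitney U for sex
(exact enumeration when both groups have $\le 8$ observations, else the
normal approximation with tie and continuity corrections). Families and
their corrections:

| family | units | correction |
|---|---|---|
| edges vs age | upper-triangle edges | Storey pFDR ($\lambda = 0.5$) |
| node strength vs age | parcels | Storey pFDR |
| edges / node strength by sex | as above | Storey pFDR |
| module within/between strength vs age | modules + module pairs, combined | BH FDR at 5% |
| single feature vs age | parcels, one family per feature | BH FDR at 5% |

The pFDR $\pi_0$ estimator uses a fixed $\lambda = 0.5$ rather than the
smoother-based estimator: it is deterministic, testable, and reduces
exactly to BH when $\hat\pi_0 = 1$. Degenerate (constant) series yield
missing statistics and are *excluded* from their correction family —
coercing them to $p = 1$ would deflate the family. Singleton modules
have no within-module strength (missing, not zero). Family sizes are
reported in the output metadata. Edge-age correlations use per-subject
MSN edge values against age, and the full edge-age $\rho$ matrix is
re-used as a similarity matrix to cluster regions by maturational
profile.

## The synthetic cohort generator

The restricted imaging data are replaced by a generator whose defaults
emulate the target cohort's statistical shape: 241 subjects, ages
uniform on 37.43-44.71 weeks postmenstrual age, balanced sexes, 150
approximately equal-area parcels, 7 mirror-symmetric spatially
contiguous modules, 8 named features. Feature values follow

$$y_{spf} = B_{m(p)f} + \gamma_f\,(a_s - \bar a)\,g(p) + \delta_f\,[\mathrm{sex}_s = M] + \varepsilon_{spf},
\qquad \varepsilon \sim \mathcal N(0, \sigma^2)\ \text{iid},$$

with $g(p) = (1 + \langle c_p, \mathrm{axis}\rangle)/2$ a linear ramp
along a configurable posterior-anterior axis. Defaults and reasons:

* **Module profiles $B$:** random mutually orthogonal rows scaled to
  norm $\sqrt F$, so each feature's between-module spread is about 1 —
  the inter-regional SD that cortex-wide z-scoring imposes on real
  features. Orthogonality makes between-module profile correlations
  near zero, so modules are identifiable.
* **Noise $\sigma = 0.5$:** inter-subject variation at half the
  inter-regional signal. At this ratio per-subject networks are noisy
  but structured — group clustering recovers the planted modules
  essentially exactly, individual subjects reproduce the group
  partition with median NVI well under 0.2, mirroring the qualitative
  finding that the modular structure is evident in individuals.
* **Age slopes $\gamma$** (per z-unit per week): SA and MI +0.05
  (clear brain-wide growth), CT/NDI/ODI +0.02, FA +0.02 (mixed in
  space via $g$), MD −0.04, MC 0 — the qualitative ordering reported
  for this age range.
* **Sex effects $\delta$:** +0.05 on CT and SA in males — small
  relative to noise, as sex effects in this period are subtle.
* **Ages uniform** over the range: the least committal choice
  supporting rank statistics (the real distribution is non-normal and
  otherwise unspecified).
* **Parcellation:** Lloyd-relaxed spherical Voronoi seeds against a
  fixed Monte-Carlo cloud (default $10^5$ points, 30 iterations);
  area weights are the assignment frequencies. The coefficient of
  variation of areas after relaxation is well under 0.15 at 50
  parcels.
* **Hemispheres** are the sign of the centroid x-coordinate on a
  single sphere. Real pipelines use two hemispheric surfaces; a single
  sphere keeps the spin test simple and is a documented
  simplification.
* **Reference classes** stand in for a cytoarchitectonic atlas: with
  `overlap = 1` a relabelled copy of the truth, with `overlap = 0` an
  independent contiguous labelling, in between a spatially contiguous
  cap of parcels is reassigned to the independent labelling. A
  contiguous (rather than scattered) reassignment keeps the blend's
  distance to the truth monotone in `1 - overlap` — scattered flips
  fragment the map and overshoot the fully independent labelling's
  NVI.

What the generator does *not* emulate: vertex-level measurement
followed by ROI averaging (values are parcel-level directly; the
downstream contract only consumes parcel means), spatially correlated
residual noise (iid is assumed and flagged — real residuals are
smooth), preterm-birth effects, and realistic MRI intensities. Passing
tests therefore demonstrate that the pipeline recovers structure of
this planted form; they do not certify behaviour under spatially
autocorrelated noise.

## Numerical choices and degenerate inputs

* z-scoring a constant subject-feature slice, a constant parcel
  profile, or a constant cross-subject series is a hard, named error —
  silently substituting zeros would bias clustering.
* Similarity matrices are validated on construction: symmetry to
  $10^{-12}$, unit diagonal and $[-1,1]$ off-diagonal for MSN/SCN
  kinds.
* Correlations are clamped to $[-1, 1]$ after floating-point round-off.
* The group matrix diagonal is fixed at 1 but never used by
  clustering (the preference replaces it).
* Every stochastic stage derives its seed deterministically from the
  global seed plus a stage tag, so adding a stage never silently
  shifts the randomness of existing ones; identical configs produce
  byte-identical outputs.

## Problem sizes used by the shipped checks

The default test suite runs the planted-module recovery at full study
scale (241 subjects x 150 parcels), spin-test calibration with 200
replicate tests of 500 rotations each on a 100-parcel scheme, FDR
calibration with 200 replicates of 1000 tests, and null-cohort
calibration of the edge/node/module/feature families with 100
replicates of a 30-subject, 24-parcel cohort. The acceptance script
reruns the full pipeline at study scale; the per-subject consistency
stage uses the first 40 subjects, and bootstrap stability uses the
full 500 draws of 20 subjects. These sizes are the package's choices
for routine verification; all of them can be raised through the same
function arguments.

## Known limitations

* iid residual noise overstates the spin test's job: with spatially
  smooth residuals the effective number of independent parcels is
  lower than the parcel count everywhere.
* The spin test carries labels at parcel level; its small residual
  anticonservatism (documented above) is inherent to rotating maps
  that share a tessellation and should be kept in mind near
  $p \approx 0.05$.
* Spearman p-values use the $t$ approximation throughout; at very
  small $n$ an exact permutation p would differ.
* The preference bisection assumes $k$ is monotone in the preference;
  plateaus can make some intermediate $k$ unreachable on a given
  matrix, which is reported as a search failure with the nearest
  achieved counts.
* No alternative community detection (Louvain, spectral) and no graph
  thresholding are provided, by design.
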