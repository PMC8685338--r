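---
title: "Surface-based regional homogeneity: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based regional homogeneity: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surfReHo)
```

## The statistic

2dReHo asks, vertex by vertex, how concordantly a cortical location and
its mesh neighborhood fluctuate. For a seed vertex the package collects
the time series of the seed and its two-ring (all vertices at edge-graph
distance 1 or 2) and computes Kendall's coefficient of concordance W.
Each of the K series is ranked over its n timepoints (midranks for
ties); with rank sums $R_i$ per timepoint and $S=\sum_i(R_i-\bar R)^2$,

$$W = \frac{12\,S}{K^2(n^3-n) - K\sum_j T_j},\qquad
T_j=\sum_{\text{tie groups}}(t^3-t).$$

W lies in [0, 1]; under independent series $E[W]=1/K$. At a regular
degree-6 vertex the two-ring holds 18 neighbors, so K = 19; one-ring
analysis (K = 7) is available via `ring = 1`. The voxel-grid analogue
(3dReHo, 26 neighbors) is deliberately not implemented — this package is
surface-only.

**"18 nearest vertices" means the two-ring.** Neighborhoods are graph
rings, not Euclidean nearest-neighbor sets: the counts 6 and 18 are
exactly the one- and two-ring sizes of a regular triangulation vertex.
Icosphere (and fsaverage-family) meshes contain 12 vertices of degree 5;
these keep their natural ring sizes (5 and 15) and W is computed over
however many series exist. Padding to a fixed K would fabricate data;
the per-vertex K is what the mesh dictates.

**Tie handling.** The tie-correction term is on by default. Continuous
fMRI data rarely tie, but the corrected form is exact when quantized
synthetic fixtures do. A zero-variance (constant) series cannot be
ranked meaningfully: it is excluded from every neighborhood it touches
(logged), and a vertex left with fewer than two usable series is masked
out rather than given a fabricated value.

## Processing order and preprocessing

The implemented order mirrors the conventional surface pipeline: discard
leading volumes (default 10) → nuisance regression → band-pass →
(projection, when starting from a volume) → 2dReHo → smoothing of the
**maps** → statistics. Smoothing is applied to maps, not time series,
because the target protocol smooths the ReHo maps; smoothing series
first would inflate W itself.

- *Nuisance model*: intercept + Friston-24 motion expansion
  ($R$, $R^2$, lagged $R$, lagged $R^2$; lag zero-filled at the first
  frame) + white-matter and CSF mean series. The global signal is **not**
  regressed by default — its removal is contested in psychosis samples —
  but the design matrix is user-extensible. Identically zero columns are
  dropped; residual collinearity is an error naming the offending
  columns, not a silent pseudo-inverse.
- *Band-pass dialect*: the protocol names only the band (0.01–0.1 Hz).
  The default filter is an ideal DFT mask (bins with
  $\text{low} \le f \le \text{high}$ kept, everything else, including
  DC, zeroed) because its gains are exactly testable: 1.0 in-band, 0
  out-of-band for bin-centered sinusoids. A Butterworth-gain variant
  (order 4) exists for users who prefer soft shoulders.
- *Projection*: vertices of the mid-thickness surface (vertexwise
  midpoint of white and pial) are mapped through a supplied
  world-to-voxel affine and sampled trilinearly. Conventions are fixed
  once: affines map world mm (RAS) to 0-based continuous voxel indices,
  voxel centers at integers. Trilinear interpolation is exact for affine
  intensity fields, which gives the module a machine-precision oracle
  (the `make_test_volume` ramp fixtures). Out-of-view vertices are
  masked out with a warning by default (`out_of_view = "fail"` to
  abort). Registration estimation (BBR etc.) is out of scope — the
  affine is an input.

## Smoothing

Geodesic Gaussian smoothing with FWHM 10 mm by default
($\sigma = \text{FWHM}/2.3548$). Distances are edge-graph Dijkstra
lengths truncated at $3\sigma$ — an approximation to exact polyhedral
geodesics that is accurate when the kernel is much wider than an edge
(the implementation warns when it is not). Kernel rows are renormalized
over masked-in vertices, so constants are preserved exactly, the output
range never exceeds the input range, and the medial wall neither leaks
in nor drains weight. On a flat regular grid the realized impulse
response has FWHM within a few percent of nominal (verified numerically
in the tests; the graph metric's anisotropy on a hexagonal lattice
bounds the error).

The global summary is the uniform mean of the (smoothed, by default) map
over the cortex mask; area weighting is a switch. Both choices are
exposed because neither is fixed by convention; on near-uniform
icospheres they differ by well under 2 %.

## Group statistics

Per-vertex two-sample t tests use the pooled-variance Student form
(the standard imaging GLM contrast; Welch is a flag), sign convention
patients minus controls. Multiplicity is handled by Benjamini–Hochberg
over all masked-in vertices of both hemispheres jointly — the joint
family is the conservative reading when a protocol says only "FDR
corrected". Significant vertices are split by t sign and grouped into
maximal edge-connected components; each cluster reports its peak
(argmax |t|), area in mm² (sum of member vertex areas, which partition
the surface) *and* member count, because "cluster size" is used for both
quantities in the literature.

Clinical association uses partial Spearman correlation: both the
regional map mean and the clinical variable are OLS-residualized on
intercept + age + sex, then their ranks are correlated; p comes from the
t approximation with $n-2-k$ degrees of freedom. Correlations run in
patients only. The region × variable family is BH-corrected, and raw
significance is reported alongside (published work sometimes reports an
uncorrected correlation; both columns make that explicit). Demographic
sex tables use Pearson's chi-square without continuity correction —
the form that reproduces p = 0.67 on a 65/28 vs 84/41 case-control
sex split; Yates is a flag.

## The synthetic world

No clinical data are distributable, so the generator *is* the test bed.
Its model: per vertex,

$$x_v(t) = \sqrt{\rho_v}\, s_{r(v)}(t) + \sqrt{1-\rho_v}\,\varepsilon_v(t),$$

where $s_r$ (one latent per region: background, or a planted cluster)
and $\varepsilon_v$ are independent AR(1) processes with coefficient
$\phi$ and unit innovation variance. Any two vertices sharing a region
latent correlate at $\rho$, so $\rho$ is a single knob that maps
monotonically to W (verified over a $\rho$ grid). Planted clusters are a
seed vertex plus its ring-k neighborhood with group offsets
$\delta_{SZ}, \delta_{HC}$; a global offset and per-subject jitters
(cluster-level SD 0.08, global SD 0.02) create between-subject variance.
Clinical covariates are rank-coupled to the linked cluster's subject
jitter by a Gaussian copula (Pearson $r = 2\sin(\pi r_s/6)$ for a
Spearman target $r_s$), then mapped through strictly increasing quantile
functions (gamma marginals), so only rank structure — all the downstream
Spearman analysis sees — is asserted.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| mesh | icosphere s = 3, r = 50 mm (642 vertices) | minutes-scale tests; 6.6 mm edges resolve a 10 mm kernel |
| n per group | 45 / 45 | desk-scale stand-in for the ~93/125 cohort |
| T, TR | 150 volumes, 2 s | protocol TR; shortened from 255 for runtime |
| $\phi$ | 0.3 | typical band-passed BOLD lag-1 autocorrelation |
| $\rho_0$ | 0.3 | baseline W ≈ 0.3 at K = 19, mid-range for cortex |
| $\delta$ | ±0.15 | yields per-vertex d ≈ 1.2–1.7 (≈ 1.5 target) with jitter SD 0.08 |
| clusters | ring-4 patches, both signs | mirrors a bidirectional group finding |

These values were fixed before the acceptance tests were run and have
not been tuned afterwards. The demographic margins of the cohort tables
(PANSS subscale means 13.3/20.7/28.2 with total = sum, illness duration
gamma with mean 16.3 y / SD 10.9 y, age ~41 vs ~38) follow published
schizophrenia case-control descriptives; the recruitment roster plants
exactly 4 patient and 1 control QC failures (motion > 2 mm/2° or
incomplete acquisition) so that quality control retains 93 of 97
patients and 125 of 126 controls with a post-exclusion sex split of
65M/28F vs 84M/41F.

**What a green test does not establish.** The generator has no
hemodynamic response, scanner noise spectrum, motion artifacts, spatial
autocorrelation beyond region sharing, or inter-subject anatomical
variability; its latents are Gaussian and stationary. Passing
calibration here shows the *pipeline arithmetic* is right and the
statistics control what they claim under the model's assumptions — not
that effect sizes from real cohorts will transfer.

## Numerical choices

- W is clamped to [0, 1] after division; a non-positive denominator
  (all-constant input) returns 0 with a warning rather than NaN.
- The vectorized map computation (sparse neighborhood incidence ×
  rank matrix) is bit-identical to the per-vertex definition; the test
  suite enforces exact agreement on whole meshes.
- Determinism: a master seed fans out to stages and subjects through a
  fixed integer derivation (modulus below $2^{31}$); identical configs
  reproduce identical outputs bit-for-bit, which the pipeline tests
  assert.
- BH ties are resolved by thresholding on the p-value itself
  (`p <= p_(k*)`), so equal p-values always share a fate.
- Geodesic truncation at $3\sigma$ discards kernel mass
  < $e^{-4.5} \approx 1\%$ per tail before renormalization.

## Acceptance-test scaling

Two statistical criteria are scaled for a single-CPU minutes budget and
documented here: the null-calibration loop runs its 200 replicates on an
s = 2 mesh with n = 12/12 and T = 60 (the rejection-rate bound is the
binomial slack formula at 200 replicates); the clinical-correlation
recovery Monte-Carlo uses 120 replicates (SE of the mean ≈ 0.008, an
order of magnitude inside the ±0.15 acceptance band) on an s = 2 mesh
with the full n = 90 patients. Full-scale single runs (n = 45/45,
T = 150, s = 3) back the detection/Dice and sign-recovery criteria.

## Known limitations

- Geodesics are graph shortest paths, not exact polyhedral geodesics;
  fine for 10 mm kernels on ≤ 7 mm edges, biased on coarse meshes.
- The NIfTI-1 reader/writer is minimal (uncompressed, float32/64,
  sform); it exists for fixture interchange, not as a general reader.
- One connected mesh per hemisphere is assumed; disconnected components
  are not rejected but smoothing and clusters will not bridge them.
- Whether the global mean should use the smoothed or raw map, and
  uniform or area weighting, is not fixed by convention; defaults are
  smoothed + uniform, both switchable.
- The permutation/cluster-mass inference family is out of scope; only
  vertex-wise BH-FDR is provided.
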