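---
title: "Methods: outline harmonics, morphospaces and disparity in stylospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline harmonics, morphospaces and disparity in stylospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stylospace` quantifies the shape of closed two-dimensional specimen
outlines — its motivating case is the head capsule plus paired piercing
stylets of neuropteran (lacewing) larvae — and compares the morphological
diversity ("disparity") of labelled groups across time slices of the fossil
record. This vignette documents the model, the tunable parameters, the
numerical decisions, and the limits of what the package's synthetic
experiments can show.

## 1. Outlines and their invariants

An outline is an ordered closed polygon with a specimen id, a group label
and a time slice (`cretaceous`, `eocene`, `miocene`, `extant`, `other`).
Three invariants are enforced rather than silently repaired: vertices are
pairwise-distinct consecutively, the polygon is simple, and storage is
counterclockwise under a mathematical y-up convention (clockwise input is
reversed, keeping the first vertex, and the reorientation is recorded in
the dataset provenance). Image-derived y-down coordinates must be flipped
at import: normalization removes rotation but *not* reflection, and a
silent mirror would change the chirality of asymmetric stylets.

Readers accept outlines with as few as 3 distinct vertices so that
hand-checkable fixtures (unit squares, decoded chain codes) remain legal;
the analysis entry point applies the stricter `validate_outline()` floor of
8 distinct vertices. Before harmonic analysis every outline is resampled to
`k = 200` points equally spaced by cumulative arc length. With the default
20 harmonics the highest frequency present is 20 cycles per revolution;
200 ≥ 2 × (2 × 20) samples keeps the discrete series comfortably clear of
aliasing while keeping the cost of validation and analysis low. The
original digitization density of published outlines is generally not
recoverable, so 200 is this package's default, not a reconstruction of
anyone else's.

## 2. Elliptic Fourier descriptors

For a closed polygon with segment steps $(\Delta x_p, \Delta y_p)$, lengths
$\Delta t_p$, cumulative lengths $t_p$ and perimeter $T$:

$$a_n = \frac{T}{2n^2\pi^2}\sum_p \frac{\Delta x_p}{\Delta t_p}
 \left[\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right],$$

and $b_n$ with sines, $c_n, d_n$ with $\Delta y_p$. The dc terms $A_0, C_0$
locate the outline; translation moves only them, which the tests assert at
1e-9. The reconstruction (inverse transform) evaluates the truncated series
at equally spaced parameter values; truncating harmonics never lowers the
reconstruction error (asserted as a monotonicity property).

A caveat worth stating explicitly: an ellipse is *exactly* one harmonic
only under the elliptic-angle parameterization. EFA parameterizes by
chord/arc length, under which a (2, 1) ellipse has first harmonic
≈ (1.828, 0, 0, 1.073) and small nonzero odd harmonics. The tests therefore
check ellipse coefficients against an independent dense quadrature of the
Fourier integrals (the idealized single-harmonic picture is asserted only
at the parameterization-appropriate loose tolerance), and use the circle —
where symmetry makes the two parameterizations coincide — for the tight
closed-form check.

### Normalization

The first-harmonic ellipse standardizes the descriptors: starting-point
phase $\theta = \tfrac12\operatorname{atan2}\!\big(2(a_1b_1 + c_1d_1),\;
a_1^2 + c_1^2 - b_1^2 - d_1^2\big)$, rotated per harmonic $n$ by $n\theta$;
if the minor axis lands in the cosine column ($b_1^2 + d_1^2 > a_1^2 +
c_1^2$ after rotation) $\theta$ is advanced by $\pi/2$ so the semi-major
amplitude is standardized; orientation $\psi = \operatorname{atan2}(c_1,
a_1)$ removed by a rigid rotation; scale divided out by
$E = \sqrt{a_1^2 + c_1^2}$. Afterwards $a_1 = 1$, $b_1 = c_1 = 0$,
$|d_1| \le 1$ and the dc terms are zeroed.

$\theta$ has two solutions $\pi$ apart (the two ends of the semi-major
axis); they differ exactly by a sign flip of all even-harmonic
coefficients. The tie is broken by making the first non-negligible
even-harmonic $a$/$d$ coefficient positive. This rule was chosen because it
is *intrinsic*: it commutes with rotation, scaling, translation, start
relabeling, and mirroring of the input. (A rule based on the sign of a
pre-rotation quantity such as $a_1$ cannot work: $a_1 = E\cos\psi$ changes
sign under a rigid rotation of the specimen, so rotated copies of the same
shape would disagree at every even harmonic.) Shapes whose even harmonics
all vanish — circles — are unaffected, as all the flippable coefficients
are zero there.

### Reflection

With counterclockwise orientation enforced, mirroring an outline acts on
the normalized descriptors by negating $b_n$ and $c_n$ for all $n$, leaving
$a_n$, $d_n$ (including the aspect ratio $d_1$) untouched; this is both
derivable from the transformation algebra and verified numerically to
1e-12. `allow_reflection = TRUE` canonicalizes the sign of the first
non-negligible $b$/$c$ coefficient, which maps a shape and its mirror image
to identical descriptors — useful when specimens were digitized in mixed
aspect. The default is `FALSE`: consistently digitized specimens keep their
chirality, which for curved stylets is real signal.

### The feature matrix

After normalization $a_1, b_1, c_1$ are constants and are dropped; $d_1$
(first-ellipse aspect ratio) is kept. With $N = 20$ harmonics each specimen
contributes $4N - 3 = 77$ features, written as
`d1, a2, b2, c2, d2, …, a20, b20, c20, d20`. Whether $d_1$ belongs in the
feature set is a genuine judgment call; it is kept here because it carries
the gross elongation of the head + stylet silhouette, and excluding it
would make slender-versus-stocky differences invisible to the morphospace.

## 3. The PCA morphospace

PCA is computed on the covariance matrix (centered, unscaled): all
coefficients share the same normalized-shape units, and correlation scaling
would inflate the influence of the near-constant high harmonics.
Eigenvalues are sample variances ($n-1$); components with eigenvalue below
$10^{-12}\times$ total variance are dropped; no further retention cutoff is
applied, and disparity downstream uses all retained components. Eigenvector
signs are fixed by requiring each component's largest-magnitude loading to
be positive, removing platform-dependent sign flips so that score files are
byte-stable. Conservation of total variance (trace identity) is asserted on
every fit at 1e-9.

Per-PC occupation is summarized as the min/max/range of the untreated (not
bootstrapped) scores for every group × time-slice combination; empty
combinations are emitted with `n = 0` and `NA` range rather than dropped,
so report tables have a fixed shape.

## 4. Disparity: sum of variances, bootstrap, rarefaction

Disparity of a subset is the sum over retained PCs of the sample variance
of its scores — the trace of the subset's score covariance. It needs
$n \ge 2$; smaller subsets are skipped with a warning (the single Miocene
record of a group should not crash a 1000-specimen run).

Uncertainty and sample-size correction use a combined bootstrap +
rarefaction: each of `n_boot = 10000` replicates draws $m$ rows *with
replacement* and records their SoV. Under the `"smaller-group"` policy
(default) $m$ is the size of the smallest eligible subset within the same
group, so a 300-specimen extant subset and a 30-specimen Cretaceous subset
are compared at a common effective size. Resampling with replacement at
size $m$ is used for the rarefaction step (rather than without-replacement
subsampling) so that the $m = n$ case is the ordinary bootstrap and the
replicate distribution is continuous in $m$; the replicate mean then obeys
$E[s^{*2}] = \frac{n-1}{n} s^2$, which the tests verify against the closed
form.

Each subset's replicate stream has its own seed derived from
`hash(root_seed, group, time_slice)` (a 31-adic string hash modulo
$2^{31}-1$), so adding or excluding one subset never perturbs any other
subset's draws, and the whole report bundle is byte-identical across runs
with the same configuration.

### Pairwise tests, and why they are labelled anticonservative

Subsets are compared with Welch two-sample t-tests *on the bootstrap
replicate vectors*, Bonferroni-corrected by the number of pairs
($p_{adj} = \min(1, p \cdot m_{comparisons})$); by default only time-slice
pairs within the same group are tested, since cross-group contrasts mix
shape differences with noise differences (`comparisons = "all"` is
available). Testing replicate vectors treats `n_boot` as the sample size,
which makes the tests sharply anticonservative: under the null (two subsets
from the same generative distribution) the rejection rate at
$\alpha = 0.05$ is far above nominal, a property the test suite reproduces
deliberately rather than "fixes", because this is the procedure the
workflow implements. All outputs carry the label
`bootstrap-replicate t-tests (anticonservative)`, and
`percentile_overlap()` offers the conservative alternative (two subsets are
distinguishable only if their central 95% bootstrap intervals do not
overlap).

Degenerate tests are defined by convention: zero variance on both sides
with equal means gives $t = 0, p = 1$; with unequal means the $p = 0$ limit
is returned and flagged.

## 5. The synthetic specimen generator

Real digitized outlines of published specimens are not redistributable in
machine-readable form, so the package generates statistically analogous
ones with known ground truth. The shape grammar is deliberately parametric
rather than traced from drawings, so every parameter has a documented
geometric meaning and recovery experiments can be scored exactly:

* **Head capsule**: a superellipse with exponent $e$ ($e = 2$ ellipse,
  larger = boxier, smaller = more diamond-like), length and width.
* **Stylets**: two prongs spliced into the anterior margin; each is a
  tapering band around a circular-arc centerline (length relative to head
  length, base width, signed total turning angle `stylet_curvature`), with
  optional sinusoidal tooth bumps on the inner edge (`tooth_count`,
  `tooth_amplitude`).

The boundary is constructed directly as one closed counterclockwise
polygon — front superellipse arc, left prong, posterior arc, right prong —
rather than by boolean union of overlapping parts. A direct construction
needs no polygon-clipping machinery, cannot produce multi-part results, and
makes the geometry exactly controllable; the costs are that prong bases
must sit on the head margin (enforced by an angular-width guard) and
overlap-style morphologies are out of reach.

Curvature is implemented *chirally*: both prong centerlines turn by the
same signed angle, so mirroring the whole shape is exactly equivalent to
negating `stylet_curvature`, which gives the reflection machinery of the
descriptor layer a nontrivial test target. With zero curvature (and any
teeth, which are mirrored) the shape is exactly bilaterally symmetric, and
its $b$/$c$ coefficients vanish. The resampling lattice is anchored at the
anterior apex so a mirrored archetype renders to the exact mirror point
set.

Individuals perturb their group archetype with independent Gaussian noise
of scale `noise_scale`: multiplicative log-normal for strictly positive
parameters (lengths, widths, exponent — preventing sign flips), additive
for the signed curvature. Each individual's draw is seeded from
`(root_seed, group, slice, index, attempt)`; draws that violate archetype
bounds or render to a self-intersecting polygon are rejected and redrawn
(logged in the ground-truth table), and an overall rejection rate above 50%
is an error advising a smaller `noise_scale`.

`default_study_design()` fixes the study conditions: four time slices with
230 / 34 / 12 / 787 specimens (1063 total), mirroring the strong
fossil-versus-extant asymmetry of the published record, spread over six
archetype groups — curved-and-toothed "owllions" and long-styleted
"nymphidae" and short-styleted "aphidlions" persisting through all slices,
straight-jawed "mantispoids" and extremely long-styleted "longnosed" only
in the Cretaceous, and slender "sisyrids" only extant. Noise scales
(0.05–0.08) were set once to give within-group shape variation visibly
smaller than between-group differences, as in the real material. Each
group's noise is constant through time, so the default design carries *no*
built-in disparity loss: it is a sampling-structure testbed, not an
imitation of the empirical result.

## 6. Orchestration and reproducibility

`disparity_analysis()` is the single fitting entry point and returns a
classed object with `print`, `summary`, `plot` (morphospace scatter,
disparity boxes, per-PC range bars), `predict` (projection of new outlines
into the fitted morphospace) and accessor methods. `run_pipeline()` wraps
it with file I/O: dataset manifest, coefficient table, scores + model JSON,
range table, disparity table, test table, and a run manifest with seeds,
parameters and per-stage record counts. CSV floats are printed with 12
significant digits through a fixed writer, making outputs byte-identical
for identical configuration and seed. Group exclusion (e.g. dropping a
morphologically extreme outgroup that would polarize the morphospace) is a
configuration list, and the PCA is refit after exclusion. Configurations
round-trip through YAML. The package is an R library; its functions and
this vignette are the operating interface, and `scripts/acceptance.R` is a
thin script over them that recomputes the headline quantities from scratch.

## 7. What the tests do and do not show

The synthetic experiments verify, at desk scale, that the machinery has the
statistical behaviour the workflow relies on: a twofold difference in
generative noise is recovered as correctly ordered disparity with
Bonferroni-adjusted p < 0.001 in ≥ 95 of 100 replicates (two groups of 30,
2000 replicates); equal-noise subsets of size 30 versus 300 give
overlapping rarefied disparity intervals (the correction for unequal
sampling does its job); disparity rises monotonically with noise scale; and
the full 1063-specimen default run is byte-stable. Problem sizes in the
test suite (n = 10–30 per subset in repeated experiments, k = 100–200,
n_boot = 200–10000) were chosen as the smallest that make these properties
sharp.

None of this validates the *biological* conclusions reachable with the
package: synthetic superellipse-and-prong silhouettes have no digitization
noise, no preservation bias within a time slice, no phylogenetic
correlation structure, and group labels that are true by construction.
Passing tests show the estimator chain is correct and well calibrated on
shapes of this kind — not that any particular empirical dataset's disparity
signal is real. Known limitations: no landmark (non-outline) support, EFA
only (no wavelet or semi-landmark alternatives), sum of variances only (no
hull volumes or pairwise-distance metrics), and plain PCA (no between-group
or phylogenetically corrected ordinations).
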