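---
title: "Counting cell divisions by photoconverted-label dilution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cell divisions by photoconverted-label dilution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement principle

`photolineage` analyses imaging experiments in which cells carry two
fluorescent reporters expressed at a fixed 1:1 stoichiometry (one
transcript, a 2A self-cleaving peptide between the two coding sequences):
a constitutive label in one compartment and a green-to-red
photoconvertible protein (e.g. Dendra2) fused to histone H2B in the
nucleus.  Brief violet illumination irreversibly converts the
H2B-Dendra2 pool of the illuminated cells.  Because chromatin-bound H2B
is long-lived and is not replenished in its converted form, every
subsequent division dilutes the converted pool approximately two-fold
between the daughters, while constitutive expression replenishes the
*unconverted* pool.  Two readouts follow:

* the **photoconverted intensity** of a nucleus estimates how often that
  cell divided since conversion: \(I_d \approx I_0 \, 2^{-d}\);
* the **colocalization** of unconverted signal with a bright converted
  nucleus reports renewed synthesis, i.e. the cell divided (or at least
  re-expressed); its absence marks a cell that has not divided.

The package implements the full chain: synthetic-tissue generation with
ground truth, nucleus segmentation above background, per-nucleus
quantification, Gaussian-mixture resolution of division-extent
populations, lineage tracking through time-lapse data, and spatial
statistics for the arrangement of the non-divided cells.

# The division-mixture model

Per-nucleus mean intensities \(x_i\) are modelled as a K-component
Gaussian mixture on the linear intensity scale,

\[ p(x) = \sum_{k=1}^{K} w_k \, \mathcal N(x \mid \mu_k, \sigma_k^2), \]

fitted by EM with seeded random restarts (means initialised at jittered
sample quantiles, variances at the sample variance, equal weights).
Restarts guard against local optima; convergence is declared when the
log-likelihood gain drops below \(10^{-8}\) (500 iterations cap).  The
number of populations is chosen by BIC
(\(-2\log L + (3K-1)\log n\)), ties resolved toward the smaller K; K can
also be forced (e.g. `k = 3`) to reproduce the fixed three-component
analysis.  We fit raw values by maximum likelihood rather than binned
histogram counts — the binning-free estimator uses the same information
without a bin-width choice.

A **halving-constrained** variant ties the component means to a single
undivided-intensity scale, \(\mu_k = \mu_0 2^{-d_k}\) for a declared set
of division counts \(d_k\); only \(\mu_0\), the \(\sigma_k\) and the
weights are free (2K parameters).  Its M-step update for \(\mu_0\) is the
precision-weighted least-squares solution
\(\mu_0 = \sum_k c_k \sigma_k^{-2} \sum_i \gamma_{ik} x_i \big/
\sum_k c_k^2 \sigma_k^{-2} n_k\) with \(c_k = 2^{-d_k}\).
`estimate_divisions()` then inverts the dilution model,
\(\hat d = \max(0, \operatorname{round}(\log_2(\mu_0 / x)))\).

Numerical safeguards: a variance floor \(\sigma_k \ge 10^{-6}
\operatorname{sd}(x)\) prevents collapse onto single points; an all-equal
sample with \(K > 1\) is rejected with an error naming the floor; nuclei
at or below background are excluded before fitting and the excluded count
is reported.

# Segmentation and quantification

The background of a channel is summarised robustly as
`level = median`, `spread = 1.4826 * MAD`; the segmentation threshold is
\(T = \text{level} + k_{bg}\,\text{spread}\) with \(k_{bg} = 3\) by
default.  Connected components above \(T\) (8-connectivity in 2D,
26-connectivity in 3D) smaller than `min_size_px = 20` pixels are
discarded, and labels are renumbered in scan order.  Interactive workflows typically specify only "above background"; the
robust global rule is the simplest deterministic reading of that phrase
and both knobs are exposed in the configuration.

Touching nuclei can be split with the membrane channel as a guide: inside
each component a seeded watershed runs on the 1-pixel-smoothed membrane
intensity, seeded at its regional minima, so components split exactly
where a membrane ridge crosses them.  The split never merges labels and
never changes the union of foreground pixels.

Quantification produces one record per label — unweighted pixel-centre
centroid in micrometres, voxel count, and per-channel mean, integrated
and background-subtracted mean intensity (clamped at 0, since these feed
the mixture).  The colocalization judgement is reduced to the scalar
ratio \(r = u/(u+c)\) of background-subtracted means: bright nuclei
(\(c \ge\) floor, default 5 spreads) with \(r < r_{low} = 0.2\) are
`non_divided`; \(r \ge r_{low}\) is `divided_or_renewed`; the rest are
`indeterminate`.  The threshold replaces a visual judgement and is a
configuration parameter, not a biological constant; the method cannot
distinguish "never divided" from "divided once with an extremely
asymmetric partition".

# Tracking

Nuclei are linked across adjacent frames by greedy globally
shortest-first one-to-one matching of centroids within a physical gate,
ties broken by label order.  A next-frame nucleus left unmatched, whose
nearest gated antecedent already has exactly one child, is attached as a
second child — a division; at most one extra child per parent per step
(mitosis is binary).  Remaining unmatched next-frame nuclei become roots
(cells entering the field); unmatched previous-frame nuclei terminate.

Two deliberate choices:

* **Gate default 15 µm** (3 nuclear diameters per frame step).  A
  2-diameter gate cannot capture a mitotic daughter displaced by half the
  daughter separation (~12 µm) plus Brownian motion, and would misreport
  every division as a track birth.  The gate is a configuration
  parameter; tighten it for denser, slower tissues.
* **Backward mode** processes the frame pairs starting from the final
  frame.  The per-pair matcher is symmetric, so forward and backward
  agree wherever the data are unambiguous (this equality is tested); a
  literal role-swapped "attach second child" rule in backward time would
  create in-degree-2 nodes after re-orienting edges, violating the forest
  invariants, so it is not used.

Greedy matching is near-optimal at the sparse densities this design
produces (photoconverted subsets are small by construction); equality
with exhaustive optimal matching is asserted on every tested instance
with up to 6 objects per frame.  There is no gap closing across skipped
frames and no appearance model.

# Spatial statistics

The "bright cells form an aligned, evenly spaced row" observation is
operationalised with two statistics over the bright-population centroids:
the RMS perpendicular residual to the best-fit line through the centroid
along the principal axis (`alignment_rms`, µm), and the coefficient of
variation of consecutive gaps between sorted projections onto that axis
(`spacing_cv`, population standard deviation over mean — stated so that
gaps {1,3} give exactly 0.5).  Both are invariant under rigid motions.
The null model places the same number of centres uniformly on the pixel
support of the region of interest (the regenerate only, because the claim
concerns organisation within the regenerating region); one-sided add-one
p-values count null replicates at least as ordered, so p is never exactly
0 and the minimal value is \(1/(n_{perm}+1)\).  The bright subset
defaults to the top mixture component, with an intensity-quantile
alternative (`quantile:0.9`) since the original selection was visual.
"Aligned" and "evenly spaced" have no standard numeric definition;
these statistics are a declared operationalisation.

# The synthetic world

The generator is first-class, tested code: it realises the biology the
analysis assumes and provides the ground truth every stage is scored
against.

**State.** Each cell carries converted, unconverted and membrane
fluorophore pools, a per-cell steady-state synthesis level, a division
count, and lineage links.  Photoconversion moves a fraction
`p_conv = 0.95` of the unconverted pool to the converted pool ("almost
all" of the label converts; the efficiency is a parameter, not a
constant).  Division splits the converted pool between daughters with
fraction \(f \sim \mathcal N(0.5, 0.5\,\text{cv})\) truncated to (0,1)
(`partition_cv = 0.05`, near-even chromatin partitioning), conserving the
sum exactly, and resets each daughter's unconverted pool to its
steady-state level — an instant-replenishment idealisation of continued
constitutive expression (a synthesis ODE is out of scope).  Converted
label decay is 0 by default (long-lived H2B) and exposed as an
exponential rate for sensitivity work.

**Expression variability.** Reporter levels vary cell-to-cell with a
symmetric truncated-normal multiplier, `expression_cv = 0.20`, identical
for both reporters in a cell (the 1:1 stoichiometry is per-transcript).
Twenty percent is a standard magnitude for constitutive transgene
expression; without it the intensity classes collapse to ~2 %-CV spikes
that no real histogram shows, and the Gaussian-mixture readout would be
exercised on an unrealistically easy problem while becoming exquisitely
sensitive to single outliers.  A symmetric (rather than lognormal)
multiplier keeps the classes Gaussian-shaped, which is the model family
the analysis fits.

**Imaging.** Nuclei render as Gaussian blobs (sd = nuclear radius,
2.5 µm) scaled by pool; membranes as ridges on the nearest-nucleus
(Voronoi) partition — the minimal model that exercises membrane-guided
splitting without tissue mechanics.  The frame is blurred by a Gaussian
PSF (0.8 µm), then passed through a camera model: Poisson shot noise at
gain 0.5, Gaussian read noise (sd 1) on a baseline offset of 10 counts,
integer ADU quantization, and clipping at zero.  The offset and the
quantization are deterministic detector properties and are applied even
when stochastic noise is disabled: without them a "noiseless" frame has a
zero-spread background, the threshold degenerates to the baseline, and
arbitrarily small blob tails 8-connect neighbouring nuclei — degenerate
semantics, not an easier test.  With the default regime the dim
five-division class sits ~8× above the detection step, so all three
classes remain segmentable above-background objects.

**Worlds.**

* `regeneration_7dpa` — one end-point frame, 1600 × 1000 µm at 1 µm/px.
  An amputation plane at x = 300 µm separates 300 stump cells (those in
  the 100 µm stripe rostral to the plane are photoconverted and
  undivided) from the regenerate: 1,500 photoconverted contributors in
  three latent division classes d ∈ {0, 2, 5} with proportions
  0.10/0.30/0.60, plus 400 unconverted-only cells.  Cells are placed by
  random sequential adsorption with an 18 µm hard core — nuclei just
  touching at threshold, like the discrete nuclei of a binarised
  segmentation figure.  A `guide` option places the d = 0 class on an
  evenly spaced line with declared jitter, emulating the aligned row of
  bright cells; it is off by default, so the default world makes no
  spatial-order claim and the permutation test reports honest
  non-significance there.
* `gastrulation_videoS1` — a 220 × 220 µm, 19-frame (20 min/frame, ~6 h)
  time-lapse: three photoconverted founders among 30 unconverted
  neighbours; the two EVL-like founders divide between the first two
  frames and the epiblast-like founder between 80 and 100 min, each
  exactly once (fixture-defined).  Cells diffuse at 0.6 µm per step with
  hard-core volume exclusion at 24 µm (gastrula-stage cells are large),
  and daughters appear 24 µm apart — one cell diameter, which also keeps
  them optically resolvable at all later frames.

Everything stochastic draws from a single RNG stream seeded by
`scenario$seed`; identical configuration and seed reproduce stacks and
truth bit-for-bit, and the caller's RNG state is restored afterwards.

**What a green test does not establish.** The generator omits features of
real data: anisotropic and depth-dependent PSFs, autofluorescence and
scattering backgrounds, nuclear shape variation and mitotic condensation,
cell death, z-motion through the focal volume, uneven illumination, and
registration drift.  Segmentation F1 ≈ 1 and exact track recovery on
this world say the *algorithms* implement their contracts, not that real
7-days-post-amputation data would be this clean.  Conversely the world is
not rigged to be trivial: classes overlap through expression noise,
partition noise and shot noise, ~1 % of nuclei are lost or merged at the
default density, and the dim class is within an order of magnitude of the
detection floor.

# Numerical and design choices

* TIFF I/O is a minimal built-in baseline codec (little-endian,
  uncompressed, float32/uint32, multi-page, JSON metadata in the
  ImageDescription): the deployment environment provides no R TIFF
  package, and the subset implemented is exactly what the pipeline
  writes and reads back.
* ROI membership is an even-odd test at pixel centres with on-edge pixels
  counted inside, so the two senses of the same polygon partition the
  nonzero pixels exactly.
* The amputation plane is an explicit parameter (hand-drawn lasso
  selections have no numeric definition), and the pipeline isolates the
  regenerate before estimating background and segmenting: isolate first,
  then segment.
* Watershed ties are broken by insertion order and pixel index; component
  labels are assigned in scan order — determinism everywhere a tool-based
  workflow was interactive.
* EM model selection reports the full BIC table, not just the winner, so
  a "at least three levels" reading (larger K) can be inspected rather
  than asserted.
* The report JSON is a pure function of configuration and seed (no
  timestamps, no absolute paths), making byte-identical determinism
  testable.

# Known limitations

Single z-plane analysis is the tested path (3D code paths exist for
labelling and watershed but the presets are 2D); the mean-intensity
readout of a thresholded Gaussian blob is a compressive function of the
true pool, so constrained-halving fits of *image-derived* means
underestimate \(\mu_0\) ratios (fit pools or integrated intensities when
that matters); greedy tracking has no gap closing, so a nucleus lost for
one frame re-enters as a new root; and the permutation null treats the
region mask as homogeneous, ignoring any anatomical structure within it.
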