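---
title: "Methods: Gaussian-mixture Monte-Carlo reconstruction from AFM height images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Gaussian-mixture Monte-Carlo reconstruction from AFM height images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmafm)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter (with units and defaults), the
numerical choices, the design decisions taken where the design was open, and
the limitations a user should know before trusting a reconstruction.

## The coarse-grained model

AFM height images are nanometer-resolution top views, so conformations are
represented at domain resolution: each chain of a hexamer is three
anisotropic 3D Gaussian kernels — *head* (coiled-coil domain), *body*
(AAA1+/AAA2+ nucleotide-binding core plus linker) and *tail* (C-terminal
domain) — giving an 18-kernel mixture
$\rho(x) = \sum_i w_i\, N(x;\mu_i,\Sigma_i)$ with weights $w_i$ (mass
fractions), centers $\mu_i$ (Å) and covariances $\Sigma_i$ (Å$^2$). Kernel
*order* is the correspondence between models: every pairwise measure
(restraints, center fitting, correlation) assumes the two models list their
kernels identically (chain A..F, and head/body/tail within a chain).

Coordinates are right-handed, in Å, with the substrate plane at $z = 0$ and
the molecule at $z \ge 0$; structures are oriented C-terminal-face down, as
adsorbed molecules present themselves to the tip. Reference models are built
from atomic structures by `load_atoms()` (PDB/mmCIF via bio3d),
`assemble_hexamer()` (Kabsch superposition of one monomer onto each chain of
a reference hexamer, using an explicit residue correspondence — deterministic
and testable, unlike sequence-based matching in a graphics program),
`orient_and_zrotate()` (seam alignment about $z$; per-image angles are a
configuration input, default 0), and `chainwise_gmm()` (mass-weighted EM per
chain, three kernels each). Kernel roles are assigned by the plurality of
responsibility-weighted mass falling in user-declared residue ranges — the
automated analogue of annotating domains on a fitted mixture by inspection.

## Pseudo-AFM rendering

`render_pseudo_afm()` draws each kernel as its Mahalanobis-level ellipsoid
$(r-\mu)^\top \Sigma^{-1} (r-\mu) = m^2$ (default $m = 2$, the two-sigma
surface). For a pixel center $(x, y)$ this is a quadratic in $z$ per kernel;
the pixel height is the largest upper root over all kernels, clipped at the
substrate. This hard-surface model is deterministic, exact (no iteration)
and cheap enough for one evaluation per Monte-Carlo proposal. A
mixture-isovalue variant (`isovalue =`) exists for sensitivity checks; it is
slower and not used by the sampler. No tip-shape convolution is applied —
the forward model is kernel rasterization only, so tip-dilation artifacts in
real data are *not* modeled. The default image geometry is 66 × 42 pixels at
4.545 Å × 5.477 Å pitch, with pixel (1,1) the lower-left pixel center.

## Image similarity

`ssim()` is the standard local-window structural similarity: Gaussian window
(11 × 11, $\sigma = 1.5$ px), $k_1 = 0.01$, $k_2 = 0.03$, with the dynamic
range $L$ taken as the joint maximum height of the two images (heights share
a physical scale, so no per-image normalization is wanted; for two all-zero
images SSIM is defined as 1). Window smoothing is renormalized at the image
borders, which makes SSIM of an image with itself exactly 1 everywhere —
the property the sampler's second gate relies on. When a molecule mask is
supplied the SSIM map is averaged over mask pixels only. Background
correction (`subtract_background()`) fits a least-squares plane to the
non-mask pixels, subtracts it everywhere and clips negatives at zero; the
exact preprocessing of any particular instrument is out of scope, and masks
are user-drawn inputs.

## Restraints

Candidate plausibility is scored on pairwise kernel overlaps. The overlap
measure is the normalized Gaussian cross-correlation
$o_{ij} = \int g_i g_j / \sqrt{\int g_i^2 \int g_j^2}$, chosen because it is
bounded in (0, 1], symmetric, equal to 1 only for identical kernels, and has
a closed form (one 3×3 solve per pair). Each restrained pair is scored with
an asymmetric harmonic centred on $\bar o_{ij}$, the *mean* of the pair's
overlaps in the two reference conformations R (closed ring) and S (spiral):
$k_{att}(o-\bar o)^2$ when the kernels have drifted apart ($o < \bar o$),
$k_{rep}(o-\bar o)^2$ when they clash. Interpolating between two references
lets the sampler reach conformations between and beyond the two known
states.

The default hexamer scheme restrains 36 pairs: the 3 intra-chain pairs of
each chain (18), and neighboring body–body, tail–tail and head–head pairs
around the ring (6 each). Default curvatures (intra 2000/2000, body–body
500/500, tail–tail 250/500, head–head 100/100; the A–F seam pairs keep their
class curvatures but with attraction scaled ×0.2) encode the qualitative
ordering — intra-chain strongest, bodies next, tails repelled like bodies
but attracted more weakly, flexible heads least restricted, seam attraction
weakest — with round numbers; all are configuration
(`default_restraint_config()`), since no quantitative values are prescribed
by the protocol this package implements.

Connectivity is a separate *hard* constraint: phantom-particle pairs mark
intra-chain kernel intersections (hinges). Each phantom sits at the
product-Gaussian mean of its pair in the trajectory's starting model and
rides rigidly with its kernel's accumulated rotation and translation. A
proposal is rejected outright if any affected pair's phantoms separate by
more than 5 Å or leave the $m_c = 3$ Mahalanobis ellipsoid of either kernel.
Hard rejection (rather than a soft penalty) reflects that connectivity is a
property of the underlying polypeptide, not a preference. Only genuinely
intersecting pairs carry phantoms: a pair whose anchor already lies outside
the containment ellipsoid of either kernel in the starting model (e.g. the
head and tail of a chain, which touch only through the body) has no hinge to
preserve and gets none.

## Two-step annealed Monte-Carlo

Each proposal modifies exactly one kernel: with probability ½ an isotropic
Gaussian center translation ($\sigma_t = 1.5$ Å), else a covariance rotation
about the kernel center by a Gaussian angle ($\sigma_r = 5°$) about a random
axis (eigenvalues — the kernel's shape — are preserved; weights are never
resampled, because they encode mass fractions). Acceptance is gated twice
with one temperature: first Metropolis on the restraint-score change
(connectivity violations reject before any scoring), then — only if stage 1
accepts — the candidate is rendered and Metropolis is applied to
$-10000 \cdot \Delta\mathrm{SSIM}$. The ×10000 scaling puts the image term
on the same scale as the restraint term so a single annealing schedule
serves both gates. Rejection at either stage restores the previous model;
SSIM is only ever computed for stage-1 survivors.

The temperature follows a cosine schedule between 1.0 and 0.2,
$T(t) = T_{min} + (T_{max}-T_{min})(1+\cos(2\pi t/P))/2$, starting hot. The
full-scale default period is $P = 10^5$ proposals against trajectories of
$1.5\times10^6$ steps (15 cycles). For desk-scale runs the period is set to
$P = \text{steps}/10.5$: the half-integer cycle count keeps roughly the same
number of reheat cycles per trajectory *and* ends the run exactly at the
temperature minimum, so the final model is a cooled state rather than a
heated one — ending a run at $T_{max}$ (any integer cycle count) would
return a deliberately randomized model.

## Selection, convergence, comparison

The two-phase protocol runs $n$ trajectories (half from R, half from S;
full scale $n = 20$, $1.5\times10^6$ steps each), pools all snapshots of
each half and keeps the models in the top 0.2 SSIM quantile — "quantile 0.2"
is read as *retaining the best 20%* (models at or above the 80th
percentile), since the selected models are explicitly the best ones. The
retained R-models and S-models are compared exhaustively by
`kernelcenter_fit()` — Kabsch on the 18 centers, then the analytic density
correlation $CC = \int\rho_a\rho_b/\sqrt{\int\rho_a^2\int\rho_b^2}$ — and
the most similar cross pair defines the converged solutions that seed phase
2; phase 2 repeats selection and pairing. Cross-pair comparison uses the
fast center fit; `cc3d_refined()` (Nelder–Mead over the six rigid degrees of
freedom, started from the center fit, never worse than it) is the reported
CC3D_density for final model pairs.

Ensembles are clustered by rasterizing every model on one common grid (joint
3-sigma bounding box + 10 Å margin, 3 Å voxels), projecting the flattened
maps onto their first two principal components, and running DBSCAN
(min_samples = 4). When eps is not given it is set to 1.1× the 90th
percentile of the k-distance curve (k = min_samples, counting the point
itself, the same convention as the core-point test): the radius that makes
about 90% of points core points, leaving isolated outliers as noise. This
replaces by-eye tuning with a reproducible rule. Each cluster is summarised
by its median member — the model closest in PC space to the coordinate-wise
median — and clusters are ranked by size.

## Numerical choices

* EM for `fit_gmm_em()`/`chainwise_gmm()` is mass-weighted; initialisation
  is a deterministic k-means++-style seeding from the integer seed, so fits
  are reproducible. Covariance eigenvalues are floored at $10^{-2}$ Å$^2$
  (collapse protection; a warning reports when the floor engages). The
  weighted log-likelihood trace is stored and is non-decreasing.
* Kabsch superposition enforces det = +1 via the SVD sign correction and
  refuses rank-deficient point sets.
* Overlap/correlation integrals are closed-form; the test suite checks them
  against independent grid quadrature (agreement far below the $10^{-3}$
  documented tolerance, since Riemann sums of Gaussians converge
  exponentially).
* Degenerate inputs: all-zero image pairs score SSIM 1 if equal (dynamic
  range floor otherwise); a trajectory of 0 steps returns only the initial
  snapshot; an all-noise clustering returns zero clusters with a warning.
* Metropolis accepts $\Delta \le 0$ without consuming randomness, so
  zero-temperature runs are exactly greedy (neutral moves still diffuse
  along score-flat directions — see limitations).

## The synthetic generator

`make_toy_hexamer()` builds parameter-driven toy hexamers for the four
conformational classes seen in AFM (closed ring; spiral with cumulative
z-rise; open, with chain F displaced radially at the A–F seam; half-spiral,
with the D–E–F trimer translated away from A–B–C so both the A–F and C–D
interfaces open). Defaults (ring radius 55 Å; per-role sizes
head (9, 16, 7), body (18, 22, 16), tail (10, 13, 7) Å at heights
50/30/10 Å) fill most of the default 300 Å image width and — deliberately —
pack adjacent chains into contact, so neighboring body/tail/head kernels
genuinely overlap (body–body ≈ 0.18): the inter-chain restraint classes only
carry information on a hexamer whose chains touch, as in the real oligomer.
The generator emulates masked, background-corrected height maps (optional
plane tilt and i.i.d. Gaussian pixel noise; mask = molecule footprint
dilated one pixel). It does **not** emulate tip convolution, scan-line
noise, drift, or adsorption-induced deformation — so passing tests show the
*algorithm* recovers models under its own forward model, not that the
forward model matches any particular instrument.

Desk-scale problem sizes used by the test suite and `scripts/acceptance.R`
(chosen once as the smallest sizes at which the corresponding property is
meaningfully exercised): zero-temperature monotonicity over $2\times10^3$
steps; parameter recovery over 3 seeds × $2\times10^4$ steps; the two-phase
protocol with 4 trajectories × $10^4$ steps per phase; clustering of 6 + 6
constructed models at 4 Å voxels.

## Known limitations

* **A top view cannot constrain what it cannot see.** Tail kernels sit
  beneath the bodies and never contribute to the rendered height map; their
  overlap restraints fix distance-like quantities only (an overlap value is
  direction-free). Their positions are therefore determined only up to the
  connectivity leash and diffuse along score-flat directions even in cold
  runs. In synthetic ground-truth experiments heads and bodies recover well
  while tail-center errors remain at the leash scale — kernel-center RMSD to
  a known truth plateaus accordingly, and tail placement in real
  reconstructions should be read as "consistent with", not "determined by",
  the image.
* **Connectivity anchors to the start.** Phantom anchors preserve the
  *starting* model's intra-chain geometry to within 5 Å. A target whose
  relative kernel geometry differs from the start's by more than the leash
  is unreachable by construction; this is intended behavior (plausibility is
  defined by the references), but it bounds how far any synthetic-recovery
  experiment can converge when kernels are perturbed independently.
* **Density correlation saturates.** For domain-size kernels, CC3D_density
  between moderately different models is already high (≈0.9); it
  discriminates coarse arrangements, not fine placement. SSIM against the
  image is the sensitive score during sampling.
* The SSIM window, restraint curvatures, annealing period and DBSCAN eps
  rule are documented defaults, not fitted constants; all are exposed in
  configuration objects.
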