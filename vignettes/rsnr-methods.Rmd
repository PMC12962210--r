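---
title: "Relative SNR for coil and position comparisons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative SNR for coil and position comparisons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem rSNR solves

Comparing the SNR delivered by two MRI receive setups is confounded by the
object: the signal of breast tissue varies strongly between fibroglandular
tissue and fat, and when the patient is repositioned (prone versus supine)
the tissue also deforms, so voxelwise SNR maps of the two setups are not
directly comparable. The *relative SNR*,

$$\mathrm{rSNR}(\mathbf{r}) \;=\;
  \frac{\mathrm{SNR}_{\mathrm{ext}}(\mathbf{r})}
       {\mathrm{SNR}_{\mathrm{ref}}(\mathbf{r})},$$

divides the SNR map of the coil under study by the SNR map of a fixed
reference — the scanner's transmit/receive body coil, whose sensitivity is
nearly uniform — acquired with the object in the *same* position. Both maps
share the voxelwise object magnetization $m(\mathbf{r})$, which therefore
cancels: what remains is the ratio of the two coils' noise performances at
each voxel, a tissue-independent quantity that can be compared across
positions distributionally (never voxel-to-voxel across a deformation).

## SNR maps by SENSE with analytic noise propagation

Each acquisition is multichannel 3D Cartesian k-space plus a noise-only
prescan block (2048 samples per channel by default), from which the channel
noise covariance $\Psi$ is estimated as $\hat\Psi = \tfrac1n \sum_k
\mathbf{x}_k \mathbf{x}_k^H$. Coil sensitivities are estimated from the
central $24\times24\times12$ region of k-space, windowed with a separable
Tukey window ($\alpha = 0.5$) to reduce ringing, zero-padded, and
inverse-transformed; maps are normalized by the root-sum-of-squares
magnitude, with phase referenced to the principal-component virtual channel,
and a support mask keeps voxels whose RSS exceeds 5% of its 99th percentile.

Reconstruction is standard SENSE. For regular undersampling by
$R = R_{\mathrm{S/I}} \times R_{\mathrm{R/L}}$ of the two phase-encode
directions (the frequency direction never aliases), each aliased set
$\rho$ with channel-by-alias sensitivity matrix $S$ is unfolded by
generalized least squares,

$$\hat{\mathbf v} = (S^H\Psi^{-1}S)^{-1}S^H\Psi^{-1}\mathbf a,$$

the per-voxel noise standard deviation is the square root of the
corresponding diagonal of $(S^H\Psi^{-1}S)^{-1}$ (scaled consistently with
the unitary DFT convention used throughout), and the geometry factor is
$g_\rho = \sqrt{[(S^H\Psi^{-1}S)^{-1}]_{\rho\rho}\,[S^H\Psi^{-1}S]_{\rho\rho}}
\ge 1$, identically 1 at $R = 1$, where the unfolding reduces to the
matched-filter combination. The SNR map is $|\hat v|/\sigma_v$ on the
support. Numerical choices: the normal matrix is inverted by Hermitian
pseudo-inverse with relative tolerance $10^{-8}$; sets that hit the
tolerance are flagged invalid rather than fabricated; the unitary DFT makes
k-space and image noise variance coincide, so all SNR statements are
internal-consistency claims, immune to the convention but fixed for
reproducibility.

Two properties are enforced by tests rather than assumed: unfolding equals
an independent whitened least-squares solve on random instances, and the
analytic noise maps agree with pseudo multiple-replica empirical noise
(hundreds of independent noise realizations pushed through the same
reconstruction) within 5% RMS at $R=1$ and $R=2\times4$.

## What the synthetic-data generator emulates

No raw multichannel data accompany the study this pipeline is modeled on,
so every input is generated:

* **Phantom.** The standard ten-ellipse head phantom, extruded to 3D by
  per-slice scaling of the ellipse set (the outer shell becomes an
  ellipsoid). Intensities are painted per ellipse from a contrast profile;
  two built-in profiles emulate T1- and T2-weighted appearance and share
  identical support by construction. Sequence physics is *not* solved —
  contrast is an intensity table, which is all the rSNR analysis needs.
* **Digital subjects.** A chest slab (elliptic cylinder) with a chest-wall
  shell, two breasts and two axillary spheres, in two independent
  parameterized geometries: prone-like (pendant, elongated
  anterior-posterior) and supine-like (flattened, spread). The breast label
  is scaled to a target volume (mL) and includes no biomechanical
  deformation model: the two positions are separate shapes, matching how
  the analysis treats them (distribution-level comparisons only).
* **Coils.** Elements are points with a loop-like magnitude falloff
  $s(d) = a^3/(a^2+d^2)^{3/2}$ (element radius $a$, normalized to 1 at the
  center) and a smooth linear phase. This captures the near/far behavior
  that drives distance-dependent SNR without full Biot–Savart integration.
  Three geometries: conformal elements spread over the skin surface by
  farthest-point sampling (supine arrays; insulation thickness 0 mm),
  paddle bars flanking each breast laterally (prone coils), and a uniform
  single-channel body coil.
* **Noise.** Circular complex Gaussian, i.i.d. across k-space samples,
  real and imaginary parts independent with half the variance each,
  channel-correlated via a configurable $\Psi$ (default
  $\sigma^2\rho^{|i-j|}$, $\rho = 0.2$).

What passing tests on these data do *not* show: robustness to real-coil
field structure, spatially correlated or non-Gaussian noise, motion, or
imperfect body-coil uniformity. The generator is a test harness for the
*analysis*, not a scanner simulator.

## The two-contrast FWHM experiment and its calibration

The tissue-independence check images one geometry with two contrasts, each
with the external array and the body coil, computes both rSNR maps, and
histograms the symmetric percent difference
$d = 100\,(r_A - r_B)/\tfrac12(r_A + r_B)$ over the valid volume (the
symmetric denominator makes the map antisymmetric under swapping
contrasts). Noiseless, the maps are identical to machine precision; with
noise, the spread of $d$ is pure noise propagation, summarized by the full
width at half maximum of its histogram (0.5-unit bins centered on zero,
half-maximum crossings by linear interpolation between bin centers; 0.5
units resolves a ≈13-wide peak with ~25 bins).

Within a contrast pair, the sensitivity maps *and* the measured noise
covariance of each coil are estimated once (from the contrast-A
acquisition) and reused for contrast B. Both are properties of the coil,
geometry and receiver chain rather than of the pulse sequence; estimating
them per contrast would inject a random global offset of order 1.5% into
the percent-difference map (each 2048-sample covariance estimate carries
≈1.1% scale error), destroying the near-zero centering the metric is
designed to have, and would break the exact noiseless cancellation.

The baseline noise level is the one free calibration of the package. The
reference study prints only the outcome FWHM values, not its noise
magnitudes, so: the external:body noise ratio is fixed to give interior
per-voxel SNR near 5:3 (array ≈ 36, body ≈ 21.5 on the default 64³
phantom with the 20-channel conformal array), and the global scale is then
frozen (`sigma_ext = 0.00888`, `sigma_body = 0.04172`) so the baseline
percent-difference FWHM sits at 12.8. The two derived conditions — both
noise variances divided by 10, and only the external variance divided by
10 — are then *predictions* of the model, not calibrations.

One structural fact is worth recording: for any fixed generative model the
percent-difference distribution is equivariant under a common rescaling of
all noise standard deviations, so dividing both variances by 10 scales the
FWHM by exactly $1/\sqrt{10}$ — from 12.8 to ≈ 4.0. A smaller value under
that condition is not reachable by any choice of the calibrated scale, and
the package reports what the model actually produces. The external-only
condition is not a pure rescaling and lands at ≈ 11.1, in line with the
noise budget argument (the spread is dominated by the larger, body-coil,
noise term).

## Region statistics

Region values are all valid rSNR voxels inside a label (breast including
skin, chest wall, axilla), treated as independent draws — spatial
correlation induced by the reconstruction is acknowledged but not modeled,
which makes the voxel-level tests somewhat liberal; conclusions rest on the
distribution summaries rather than single p-values. Percentiles use the
linear-interpolation definition (type 7), fixed for reproducibility. The
two-tailed bootstrapped percentile-difference test draws `n_boot` (default
10,000, seeded) resamples with replacement from each group, forms
$d^\* = q_p(a^\*) - q_p(b^\*)$ for $p \in \{5, 25, 50, 75, 95\}$, and uses
$p\text{-value} = 2\min(\#(d^\*\le 0)+1,\ \#(d^\*\ge 0)+1)/(B+1)$ at
$\alpha = 0.01$. No multiple-testing correction is applied, matching the
per-test reporting convention of the reference analysis (a Bonferroni
switch exists in the test's `alpha` argument for users who want it).
Erosion robustness uses slicewise disk erosion (1- and 2-pixel radii) of
each region independently. Breast volume is voxel count times voxel
volume; the supine:prone median-ratio trend against volume is an ordinary
least-squares line with the count of points above the $y = 1$ reference.

## Distance-from-coil analysis

Element geometries are point sets: conformal elements are their centers;
prone paddles are bars sampled at voxel pitch on planes one voxel lateral
to each breast's bounding box (whether bars flank each breast or the whole
breast extent is configurable; the default flanks each breast). The
distance map is the exact Euclidean distance from each voxel center to the
nearest element point; element extent deliberately enters only through the
sensitivity falloff. Profiles bin valid rSNR voxels into half-open 2 mm
distance bins labeled by the left edge, reporting per-bin median rSNR and
voxel counts per region and pooled.

## Problem sizes and reproducibility

Default problem sizes: the phantom experiment runs at 64³ with a
20-channel array (five seeds per noise condition); the position comparison
uses 64×48×40 grids at 5 mm, three subjects of 800/1400/2200 mL, a
60-channel supine conformal array against 16-channel prone paddles, and
accelerations 1×1 and 2×4. Oracle suites run on 16³-scale instances where
brute-force references are exact. All randomness flows from one master
seed through a counter-based Lehmer expansion (`derive_seed`), so every
stage seed is logged and reproducible; identical configuration and seed
give bit-identical k-space and reports.

## Known limitations

* The two digital-subject geometries are stylized; axillary anatomy in
  particular is a placeholder sphere pair, so axilla-region results should
  be read as pipeline checks, not anatomy.
* The body coil is exactly uniform here; real body-coil shading would fold
  into rSNR as a smooth multiplicative field.
* Voxelwise independence in the bootstrap is optimistic under SENSE
  reconstruction, which correlates neighboring voxels.
* K-space containers serialize as RDS plus NIfTI/JSON/CSV sidecars; no
  HDF5 writer is provided.
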