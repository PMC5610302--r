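---
title: "Methods: lesion volumetry and coil dosimetry in elfdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion volumetry and coil dosimetry in elfdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elfdose)
```

## What the package models

`elfdose` implements the computational chain behind a pulsed
extremely-low-frequency magnetic field (ELF-MF) stimulation study in acute
ischemic stroke: lesion volumes are measured on pre-treatment
diffusion-weighted MRI (DWI) and on 1-month post-treatment T2 FLAIR by
seeded region growing; the volumetric endpoints are the FLAIR−DWI mismatch
and the FLAIR/DWI ratio; clinical state is tracked with NIHSS, Barthel
Index and modified Rankin Scale over five visits; and the magnetic dose
delivered to the lesion by a single-turn rectangular stimulation coil is
estimated magnetostatically per voxel. Patient images are replaced
throughout by a synthetic phantom generator with analytic ground truth, so
every stage is testable end to end without any data download.

## Synthetic phantoms

A phantom is a uniform background (default intensity 100) containing one
hyperintense axis-aligned ellipsoidal lesion (default intensity 200, i.e.
100% contrast) plus additive Gaussian noise (default sd 5, or 2.5% of the
lesion intensity). A voxel belongs to the truth mask iff its *centre* lies
inside the ellipsoid — no partial-volume weighting — so a brute-force count
of voxel centres is an exact oracle and the analytic volume
$\tfrac{4}{3}\pi abc$ bounds the discretization error. The default grid is
$164 \times 238 \times 36$ voxels at $(1, 1, 5)$ mm, a head-sized extent
with the anisotropic slice thickness of clinical axial series; the default
pre/post semi-axes, $(18, 14, 10)$ and $(16, 13, 9)$ mm, give volumes of
roughly 10.5 and 7.8 cm³, in the range of the published cohort and with
the shrinkage its 120-minute group showed.

Choices made deliberately simple: the lesion is an ellipsoid (real infarcts
are irregular; a closed-form truth is worth more here than realism), noise
is Gaussian rather than Rician (the inclusion rule below is
intensity-relative, so the distinction is immaterial at the contrasts
tested), and there is no bias field, mass effect or diffusion physics.
Passing phantom tests therefore demonstrates correctness of the
*computational chain*, not segmentation performance on clinical MRI.

## Seeded region growing

Growth starts from operator-chosen seed voxels. A voxel of intensity $I$
joins the region of a seed with intensity $I_s$ when

$$|I - I_s| \le \theta \, I_s, \qquad \theta = 0.20 \text{ by default,}$$

and is connected to it through the chosen neighbourhood. The band is
symmetric because a purely one-sided rule ($I \ge 0.8 I_s$) would never
stop on the bright side of a hyperintensity; the one-sided variant remains
available (`band = "lower"`) for sensitivity analysis. Each seed uses its
*own* intensity, and multiple seeds combine by union.

Growth is section-by-section: each seed's region is confined to the seed's
axial slice, with 8-connectivity in-plane by default (4-connectivity
optional), mirroring how lesions are outlined slice by slice; a volumetric
mode (26- or 6-connectivity) is available behind a flag. The implementation
iterates masked binary dilation to a fixed point, which makes the result a
pure function of the predicate set and the seed — provably independent of
traversal order; the tests confirm it against explicit depth-first and
breadth-first flood fills. Intensities are used as stored (no
normalization or bias-field correction), and voxel indices are 0-based
with physical coordinates at voxel centres.

On phantoms, seeds are placed automatically: one per slice intersecting
the truth mask. When the intensity volume is supplied, the seed is the mask
voxel whose intensity is closest to the slice's median lesion intensity —
a surrogate for an expert picking a *representative* lesion voxel rather
than a random one, which matters because the whole inclusion band scales
with the seed intensity: a seed drawn from the noise tail shifts the band
and silently erodes the segmented volume. The expert's manual-correction
pass is modelled by `edit_mask()` (set union of additions, set difference
of removals, removal winning on overlap).

Volumes are voxel count × pixel spacing × slice thickness, reported in
cm³.

## Volumetric endpoints and clinical scores

The two endpoints are `mismatch = flair_post − dwi_pre` (cm³) and
`rate = flair_post / dwi_pre`; a negative mismatch (equivalently rate < 1)
classifies the lesion as `reduced`, positive as `grew`, and exactly zero —
a case the cohort does not contain — as `unchanged`, avoiding an arbitrary
tie-break. Report files round mismatch and rate half-away-from-zero to two
decimals, matching the convention of the published table; internal values
keep full precision.

The bundled six-patient fixture reproduces the published per-patient
values. Two caveats are coded in rather than papered over: patient 5's
12-month visit is absent (`NA`, never 0, and propagated as absent by
`score_change()`), and patient 1's row is problematic twice over — the
clinical scores are typographically ambiguous in the source (the record is
flagged `scores_unverified`) and the printed FLAIR/DWI rate (3.89) is
inconsistent with the printed volumes (7.62/7.12 ≈ 1.07). Patient 3's
printed rate (1.35) also differs in the last digit from the recomputed
ratio (1.36), implying the authors divided unrounded volumes. The package
always reports ratios recomputed from the volumes, and the exact-match
tests cover the internally consistent cells (mismatch for patients 2–6,
rate for patients 2, 4, 5, 6).

## Coil magnetostatics

The stimulation coil is modelled as an ideal filamentary single-turn
rectangular loop, 14 × 10.6 cm, driven at 240 A — the current that
produces about 2 mT at the coil centre, matching the device's measured
peak of 1.8 ± 0.2 mT. The field of each straight segment is the exact
closed form, written in the singularity-robust two-ray form

$$\mathbf B = \frac{\mu_0 I}{4\pi}\,
  \frac{(r_1 + r_2)\,(\mathbf r_1 \times \mathbf r_2)}
       {r_1 r_2\,(r_1 r_2 + \mathbf r_1 \cdot \mathbf r_2)},$$

with $\mathbf r_1, \mathbf r_2$ the vectors from the segment ends to the
field point; the coil field is the sum over segments. Because the kernel
is exact, a flat rectangle is evaluated *exactly* with 4 segments;
discretization only matters for warped coils, which default to 720
segments. Two independent closed forms — the rectangle's centre field
$\mu_0 I \sqrt{a^2+b^2}/(\pi a b)$ and its on-axis field — plus adaptive
quadrature of the Biot–Savart integrand serve as oracles in the tests.
Magnetostatics suffices because tissue at these frequencies and
conductivities (edema σ = 1.7 S/m, carried as metadata only) does not
perturb the magnetic flux density; induced electric fields and SAR are out
of scope.

The flexible coil's conformity to the head is emulated by wrapping the
14 cm dimension onto a cylinder — radius = mean coronal head curvature,
default 90 mm, configurable because the published warping procedure is not
exactly reproducible — via the arc-length-preserving map
$(x, y, 0) \mapsto (R\sin(x/R),\, y,\, R(\cos(x/R) - 1))$. The flat coil
is recovered as $R \to \infty$. Field evaluation refuses points within
1 mm of the conductor (no regularization): no physically meaningful field
point in this use case is that close to the winding.

Units are SI internally (m, A, T); reports use cm and mT, the units of the
published tables. The pulse train (75 Hz, 1.3 ms rectangular pulses,
1.8 mT peak, duty fraction 0.0975) is carried as a waveform object;
dosimetry reports the field amplitude, not a time integral.

## Lesion dosimetry

For a lesion mask overlaid on the field, the package reports the min/max
Euclidean distance from the *coil centre point* to lesion voxel centres
(the convention of the published distance table; a nearest-conductor-point
mode exists behind a flag), the min/max $|\mathbf B|$ over lesion voxels,
the fraction of lesion voxels at or above the biological threshold, and a
peak-based pass/fail against that threshold — default 1 mT, the minimum
flux density reported to upregulate A$_{2A}$ adenosine receptors in
preclinical work, with an inclusive boundary.

A discrepancy is documented rather than tuned away: for a flat coil, the
on-axis field at the cohort's largest lesion distance (6.7 cm) is about
0.79 mT, below the 1.0 mT minimum the published dose table reports. The
published values come from per-patient warped-coil placements inside an
anatomical head model that is not publicly reconstructible, so
cell-by-cell reproduction of the field extrema is out of reach; the
package's field model is instead validated against closed forms,
quadrature, and physical invariants (linearity, orientation reversal,
divergence-free-ness, monotone axial decay, warp flat-limit).

## Pipeline and reproducibility

`validate_config()` normalizes a YAML (or list) configuration — rejecting
unknown keys, requiring exactly one input source (NIfTI pair, phantom
specification, or the cohort fixture), and filling defaults — and
`run_pipeline()` executes segment → volumetrics → field → dose → report,
writing masks and the $|\mathbf B|$ map as NIfTI, CSV reports, the coil
vertex list, and a JSON manifest (config echo, package version, seed,
output checksums; no timestamps). Identical config and seed give
byte-identical outputs — NIfTI files are written uncompressed for exactly
this reason — and any stage failure removes partial outputs and names the
stage. All randomness flows from the config's single `rng_seed` plus the
phantom specs' own seeds.

The default flat coil is placed on the lesion's in-plane axis 5 mm below
the first slice, i.e. just outside the volume, standing in for a coil
resting against the head surface nearest the lesion; the position is
configurable (`coil$center_mm`).

Problem sizes in the test suite are deliberately modest — phantoms of
roughly $40^2 \times 12$ to $64^2 \times 16$ voxels, 20 noise replicates
for the recovery check, 720-segment warped coils — chosen so the full
suite exercises every stage in seconds while leaving the discretization
fine enough for the stated tolerances (truth-mask volume within 2% of the
analytic ellipsoid at 1 mm spacing; recovered volume within 5% under 5%
noise; warp length preservation within 0.1%).

## Known limitations

* The phantom omits Rician noise, bias fields, irregular lesion shapes and
  partial-volume effects; recovery results do not transfer quantitatively
  to clinical MRI.
* The coil is a zero-cross-section filament; wire gauge, inductance and
  drive electronics are not modelled.
* Dosimetry reports flux density only; induced electric field, eddy
  currents and any tissue response are out of scope.
* No inferential statistics: with six patients the published study is
  descriptive, and the package stays descriptive too.
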