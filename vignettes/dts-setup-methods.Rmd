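---
title: "Short-arc tomosynthesis for clip-based patient setup: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short-arc tomosynthesis for clip-based patient setup: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Breast-cancer patients are set up for radiotherapy by aligning surgical
clips near the tumor bed with their planned positions. Orthogonal kV
radiographs often fail at this — clips overlap ribs or each other, and
scatter buries small clips — while full cone-beam CT costs dose, time and
gantry clearance. Digital tomosynthesis (DTS) is the middle ground: a
pseudo-3D volume reconstructed from a short gantry arc (a few degrees to a
few tens of degrees) of cone-beam projections. In-plane resolution is
excellent; depth resolution is poor and anisotropic. The pipeline in this
package simulates and evaluates the full setup chain:

1. **Phantom** — a water-equivalent digital body with embedded clip
   cylinders (`preset_phantom()`, `build_phantom()`), rigidly displaced by
   a known couch shift (`apply_shift()`).
2. **Acquisition** — cone-beam line integrals over a short arc
   (`acquire_arc()`), with additive Gaussian noise on the line integrals.
3. **Treatment DTS** — shift-and-add back-projection onto beam-aligned
   depth planes plus a selective-plane deblurring step
   (`reconstruct_treatment_dts()`).
4. **Reference DTS** — the planning CT resliced into the beam frame,
   reprojected into virtual projections (DRRs), and reconstructed through
   the *same* back-projection/deblurring path
   (`reconstruct_reference_dts()`), so both volumes share the limited-angle
   artifact structure; matching degrades badly if they do not.
5. **Registration** — Gaussian prefilter, zero-mean normalized
   cross-correlation of a clip-centered template over a bounded search
   region (`match_template()`), then weighted least-squares triangulation
   of two or more arcs into one 3D couch shift (`triangulate()`,
   `register_dts()`).
6. **Evaluation** — per-axis |found − applied| against the known shift
   (`evaluate_error()`), swept over arc length, arc separation, slice
   spacing and clip density (`run_sweep()`).

# Geometry and conventions

Room coordinates are mm with the isocenter at the origin: x lateral
(patient-left positive), y longitudinal (superior), z vertical (anterior).
Gantry angles follow IEC 61217 (0° source above the isocenter, increasing
toward patient left). The beam frame of an arc with middle angle
$\theta_c$ has $w$ along the central ray (source → isocenter),
$v = \hat{y}$, and $u = w \times v$; DTS volumes are stacks of $(u,v)$
slices along $w$. For two arcs the angle between their $w$ axes equals the
arc separation $\theta_{c1} - \theta_{c2}$.

Two geometry presets exist: `"obi"` (source–isocenter 1000 mm,
source–detector 1500 mm — the standard clinical kV imaging chain, and the
default) and `"fig1"` (500/1000 mm, magnification 2). The short geometry
appears in some descriptions of kV imaging arms; the two disagree and
neither is privileged by the physics here, so both are presets and the
clinically standard one is the default. The detector defaults to
300 × 300 mm at 1 mm pitch, sized to cover the reconstruction volume at
magnification with applied shifts.

# Shift-and-add reconstruction

Projections are acquired at angles $\theta_c \pm \delta\theta/2$ in steps
of 0.5° (so a 10° arc has 21 projections; clinical frame spacing is of
this order, and the step is configurable). Each projection pixel is the
ray integral of $\mu = \mu_\mathrm{water}(1 + \mathrm{HU}/1000)$, clamped
at zero, sampled trilinearly at steps of half the smallest voxel size;
rays are clipped to the volume bounding box. $\mu_\mathrm{water}$ defaults
to 0.02 mm$^{-1}$, a typical effective value at kV energies.

Back-projection (`backproject()`) follows shift-and-add semantics: for
each depth plane (spanning a 150 mm initial depth, isocenter-centered, odd
slice count) and each in-plane voxel, the value is the mean of the
projection images sampled where the source–voxel ray meets the detector.
A structure lying in a plane is in focus there; elsewhere it smears into a
fan of copies spread along the arc direction, by roughly
$\Delta d \tan\phi$ for depth offset $\Delta d$ and angular offset $\phi$.
Voxels that fall off the detector in some projections average over the
rest and carry a coverage count — they are never silently zero-filled.

The in-plane grid is reconstructed with a 12 mm margin beyond the final
60 × 60 mm field and cropped after deblurring, so warp edge effects stay
outside the delivered volume. The treatment volume keeps 75 mm of final
depth, the reference 33 mm; the extra initial depth exists to supply
out-of-plane slices to the deblurring window.

# Deblurring: design

The deblurring used by commercial DTS software is proprietary; this
package implements a selective-plane-removal scheme chosen to reproduce
the qualitative behaviors that matter for registration studies. For
output slice $i$, every initial slice $j$ inside a centered window
covering `deblur_fraction` of the initial stack — but outside a *guard
band* around $i$ — is warped to slice $i$'s geometry along the exact
back-projection rays (for each projection angle, a perspective scaling
about the source footprint; this is the transformation under which
shift-and-add spreads out-of-plane structure). The mean of all warped
contributions is the out-of-plane estimate and is subtracted.

The guard band is derived from the *coherent fraction* $f(\Delta d)$: the
share of the arc's back-projected copies of a point that land within one
in-plane pixel of the true position at depth offset $\Delta d$. Offsets
with $f \ge 1/2$ carry mostly-focused duplicates of the in-focus content;
subtracting them would cancel the signal itself, so they are excluded.
The guard band therefore widens for short arcs and narrow pixels — exactly
the offsets over which a short arc cannot distinguish depth anyway.

Properties of this design, all exercised by the test suite:

* an out-of-plane point feature's leakage into a distant in-focus slice is
  mostly removed (over half, typically ~80%, of its amplitude);
* using the whole initial stack (`deblur_fraction = 1`) gives a smoother
  background than a 20% window, because the estimate is averaged over more
  slices and cancels more of the correlated streak/noise field;
* a window that contains no slice beyond the guard band degenerates to the
  identity;
* depth elongation (slices in which a clip is visible) and background
  noise both shrink monotonically as the arc lengthens, while in-plane
  clip contrast does not improve — the classic short-arc trade-off.

Because the estimate is a mean with gain one, structure that extends
through the whole stack (the body, the DC level) is subtracted once, not
amplified; the background of a uniform object reconstructs to a flat
level. The depth profile of a clip remains wider than what a matched
deconvolution would give — the package's slice-span numbers for a 6 mm
clip at 1 mm spacing come out near 40 slices rather than the teens; depth
localization is delegated to triangulation, which does not use the depth
axis at all by default.

# Registration

Both volumes are smoothed per-slice with an isotropic in-plane Gaussian
(`gaussian_sigma`, default 1.5 mm — unstated in clinical practice; chosen
to be of the order of the reconstruction pixel so it equalizes residual
resolution differences without erasing 1 mm clips). The template is a
24 mm cube cut from the reference, centered on the clip centroid: for
phantom-built volumes the known clip layout supplies the centroid (this is
the simulation counterpart of the user drawing the ROI at planning); as a
fallback a thresholded bright-structure centroid of the central field is
used. Zero-mean NCC is evaluated on the integer voxel lattice within a
15 × 15 × 15 mm search region, the peak refined per axis by a quadratic
fit over its neighbors (clamped to half a voxel), ties broken toward the
smallest displacement. A peak pinned to the outermost *in-plane* lattice
node invalidates the match — the true shift may exceed the region. The
depth lattice is far coarser (one node per slice spacing, five nodes at
the 3 mm default), so an outermost-node test there would reject perfectly
legitimate 5 mm depth shifts; depth-edge peaks are only recorded
(`depth_on_boundary`), and the depth component is the one triangulation
discards anyway. Matches below `min_ncc` (default 0.3, operationalizing
"correlation failed") are excluded from triangulation.

Triangulation solves $u_a \cdot s = d_{u,a}$, $v_a \cdot s = d_{v,a}$ over
the valid arcs $a$ by weighted least squares; the per-arc depth equations
$w_a \cdot s = d_{w,a}$ enter at weight `w_depth`, default 0, because a
single DTS volume's depth estimate is unreliable. With two arcs the
in-plane system has rank 3 and inverts exact inputs to machine precision;
its conditioning (reported as the singular-value ratio) degrades as
$1/\sin(\mathrm{separation})$, which is why 10° separations show 1–2 mm
depth errors while ≥20° separations stay sub-millimeter. With one arc the
system is rank-deficient: the result is flagged not 3D-valid and the depth
comes from that arc's own (poor) depth match.

`score_arc_orientation()` implements the planning-stage arc check: clip
centers are projected into the beam's-eye view; any pair closer than 3 mm
flags an overlap (clips merge into one blob and mislead the correlation),
and fewer than three well-separated clips flags an insufficient layout.
The score is the minimum pairwise BEV separation among the retained clips.

# The synthetic phantoms

The rectangular phantom is a 120 × 200 × 40 mm water box (HU 0) with five
1 × 4 mm clips (HU 1200 by default, overridable to the 400–1500 range
seen clinically) spread within ±10 mm of the isocenter with ≥3 mm BEV
separation at the tangential arcs. The breast phantom is a hemiellipsoid
dome (100 × 100 × 60 mm bounding box) with the same clips — the physical
breast mold it stands in for has no published dimensions, so the preset is
representative only. Bodies are rendered with anti-aliased faces and clips
with supersampled partial-volume fractions, so rendering is deterministic,
sub-voxel shifts conserve the clip signal to better than 1%, and line
integrals match physical extents.

Applied shifts are drawn uniformly in [−5, 5] mm per axis — inside the
±7.5 mm search half-width for the tangential arcs — with 5 repeats per
condition in the stochastic studies. Noise is additive Gaussian on the
line integrals (σ = 0.01 by default, a few percent of a typical water
path) rather than Poisson on counts: it keeps the chain linear and
exactly seedable, which the reproducibility contracts require.

What the phantoms deliberately omit: ribs and heterogeneous anatomy (so
clip–rib overlap can only be *scored*, not simulated), scatter, beam
hardening, detector lag, breathing motion, breast deformation and clip
migration. Passing accuracy tests here therefore demonstrates the
geometric and algorithmic soundness of the chain — reconstruction,
matching and triangulation recover known rigid shifts under realistic
noise — not clinical performance on deformable anatomy.

# Numerical choices

* Grids are isocenter-centered with odd voxel counts, so one voxel center
  sits exactly on the isocenter; "final extent / pitch" rounds up.
* Ray integration uses the midpoint rule at ≤ half-voxel steps after
  bounding-box clipping; the accuracy contract is ±1% on slab oracles.
* Trilinear interpolation everywhere (shifting, reslicing,
  back-projection sampling); round trips are exact on constant regions.
* The deblurring window is centered; its placement within the initial
  stack was an open choice and a centered window keeps the estimate
  symmetric in depth.
* NCC ties break toward the smallest displacement magnitude, then
  lexicographically, making degenerate flat correlation surfaces
  deterministic.
* Seeding saves and restores the caller's RNG state, and sweep cells
  derive per-cell seeds from the configuration seed, so identical
  configurations reproduce bit-identical results.

# Study problem sizes

The accuracy studies in the test suite run at the full clinical scale
(1 mm phantom voxels, 300 mm detector, 0.5° steps) for the headline
two-arc conditions, and at reduced scale where a full grid is swept: the
table-shaped separation × arc-length sweep uses a 200 mm detector and 1°
projection steps with one shift per cell, and the slice-spacing study uses
a compact 70 mm phantom. These sizes are the package's own choices for a
desk-scale reproduction; the quantities they measure (bounds and monotone
behaviors) are scale-robust, which the full-scale headline runs confirm.

# Limitations

* The deblurring is a defensible stand-in with the right qualitative
  behavior, not a reproduction of any vendor's filter; absolute image
  quality metrics (contrast values, slice-span counts) are
  implementation-specific.
* Only rigid translations are registered; rotations are out of scope.
* Depth accuracy from a single arc is poor by construction and the
  package reports it as such (`valid_3d = FALSE`); always acquire two
  arcs separated by ≥20° when depth matters.
* The hemiellipsoid breast preset is a geometric stand-in, not a
  validated anthropomorphic model.
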