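---
title: "Morphometry of the optic-nerve subarachnoid space: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of the optic-nerve subarachnoid space: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The subarachnoid space (SAS) surrounding the optic nerve (ON) is a
CSF-filled annulus bridged by trabeculae, septae and pillars, all lined by
meningothelial cells (MECs). Because MECs secrete into and clear material
from the CSF, the area of the CSF-facing surface they cover bounds their
possible contribution to CSF homeostasis. Micro-CT of an osmium-fixed
nerve resolves this microstructure at sub-micron scale; quantifying it
requires a chain of image-analysis stages, each of which this package
implements and validates at desk scale:

1. **Tiling** — overlapping tomography tiles are registered by phase
   correlation and blended into one seamless volume.
2. **Enhancement** — a curvelet-style Fourier filter bank suppresses
   smooth background gradients and thin fixation artifacts while keeping
   the trabecular scales.
3. **Segmentation** — a hard threshold plus connectivity and Euclidean
   morphology yields three disjoint compartments: ON, SAS microstructure,
   CSF.
4. **Geometry** — a sub-voxel signed Euclidean distance field `phi` of the
   CSF foreground drives volumetry (integral of a mollified step of
   `phi`) and surface extraction (triangulated zero level-set).
5. **Morphometry** — model-independent local thickness: at every voxel,
   the diameter of the largest inscribed ball containing it. Applied to
   the microstructure it is *trabecular thickness*; applied to the CSF it
   is *trabecular separation*. Large separation basins are censused as
   intertrabecular fluid spaces.
6. **Report** — CSF volume and interface area with the microstructure in
   place and digitally removed; their ratios are the *surface
   amplification factor* and the *microstructure volume fraction*, with
   angular renormalization `360/(360 - angle)` when a damaged sector is
   discarded.

Every stage is validated against a seeded synthetic phantom whose
geometry has closed-form volume and area.

## The phantom and what it does (not) emulate

`phantom_spec()` describes a nerve cylinder (radius 28 µm by default)
inside a dural wall (inner radius 68 µm, extending to the grid edge),
with capsule-shaped trabeculae bridging the 40 µm annulus, optional
partial septae, additive Gaussian noise, fascicle-scale internal tissue
texture, bright homogeneous membrane linings (the MEC layers) on the
CSF-facing walls, and thin bright filaments imitating fixation damage.
Default sizes are desk-scale (192³ voxels at 1 µm) rather than the
multi-terabyte scale of a real acquisition; radii and counts were chosen
once so that every structure class is present and resolvable:

* trabecular radii 4–10 µm at 1 µm voxels keep the thinnest structure at
  ≥ 4 voxels radius;
* trabeculae keep ≥ 14 µm of clear surface-to-surface separation so that
  neighboring tubes remain individually resolvable at the segmentation's
  consolidation scale (6 µm);
* the annulus gap (40 µm) accommodates the largest inscribed balls of the
  thickest trabeculae away from the junction regions;
* the tissue texture (amplitude 0.12, correlation length 3 µm) stands in
  for the fascicle-scale contrast of real nerve tissue. It is essential:
  a band-pass filter removes the bulk (low-frequency) response of any
  structure much larger than its pass band, so large compartments are
  segmentable only through their internal texture. The membrane linings
  are left untextured — they are dense, homogeneous cell layers — which
  also keeps the wall response watertight.

Partial volume is modeled by 2× supersampling of boundary voxels, giving
the sub-voxel intensity ramps that the level-set volumetry exploits. The
phantom does **not** simulate acquisition physics (ring artifacts,
beam hardening, detector noise correlations), tilt-series artifacts, or
biological heterogeneity of trabecular shape (vela, pillars); passing
its tests therefore demonstrates correctness of the measurement chain on
idealized geometry, not robustness to every failure mode of real data.

The analytic truth records (`analytic_solid_volume_um3`,
`analytic_interface_area_um2`) are computed from the closed-form
cylinder/capsule/slab formulas of the generating primitives, with
junction holes subtracted at first order (`pi r^2 / cos(angle)` per wall
crossing). They are exact when primitives do not intersect each other;
the generator's separation constraint enforces this for trabeculae.

## Numerical choices

**Signed distance.** `phi = (distance to background) − (distance to
foreground)` between voxel centers, in µm, with half a voxel subtracted
on each side so the zero level sits midway between opposing labels. The
field is 1-Lipschitz within each side; across the interface the discrete
convention can exceed the Lipschitz bound by at most `(sqrt(3) − 1)`
voxels, which the property tests allow for.

**Volumetry.** The mollified step `U_eps` is the piecewise-linear ramp
with `eps` defaulting to one voxel. On a digitized ball of radius 20
voxels the volume is accurate to ~0.3 % and the error at least halves
when the voxel size halves (generic, off-lattice placement; exactly
lattice-centered spheres show fluctuation-dominated errors that converge
irregularly).

**Meshing.** Marching tetrahedra on the Freudenthal 6-tetrahedra
decomposition, the same diagonal in every cell: all topological
ambiguities are resolved deterministically and the mesh is watertight
away from the domain boundary (no cap faces are added where the
foreground is clipped). Because the zero level-set of a binary-derived
distance field is bumpy at the voxel scale — meshing it raises a
sphere's area by ~8 % — vertex placement uses a copy of `phi`
regularized with a Gaussian of 0.8 voxel; volumetry always uses the raw
field. With this choice a radius-20 sphere meshes to −0.3 % area error
and planar half-spaces remain exact to machine precision (a Gaussian of
a linear field is the same linear field away from the boundary).

**Local thickness.** The inscribed-ball radius at a candidate center is
its Euclidean distance to the nearest background voxel center, so a
digitized ball of radius `r` reads `2r` (± a voxel) everywhere inside,
and a lone voxel reads 2 voxels. The accelerated path sorts candidate
centers by radius and paints their digital balls, skipping any center
whose ball is *provably* contained in an already painted one; the
containment certificate `sqrt(A) ≥ sqrt(B) + sqrt(R)` is evaluated in
exact integer arithmetic on the squared quantities, so the result is
voxel-identical to the brute-force oracle (`brute_force_thickness()`),
which evaluates the definition literally and shares no code with the
fast path.

**Census.** Separation basins above the diameter threshold are split by
a seeded watershed on the separation field after h-maxima suppression
(default depth: two voxels). The equivalent diameter of a space is its
maximal separation — the largest inscribed ball — consistent with the
thickness definition; ties in the flood order are broken by voxel index,
so the census is deterministic.

## Design decisions in the imaging chain

**Band placement.** The filter bank partitions Fourier magnitude into a
low-pass residual, `octaves` dyadic rings (cos² bumps in log-frequency,
an exact partition of unity), and a Nyquist-side residual; rings carry
power-cosine angular wedges about 11 deterministic spiral-of-hemisphere
axes, normalized so each ring's wedges sum to one. Defaults: 4 octaves
spanning wavelengths 3–48 µm, low-pass and Nyquist residuals at gain 0,
finest ring at 0, second-finest at 0.25. The zeroed low-pass removes
smooth background gradients; the suppressed sub-trabecular rings carry
voxel noise and the thin fixation filaments (their contrast-to-noise
against trabeculae more than doubles at the sub-micron pixel pitch of a
real acquisition). Before the transform the mean and the best-fit
affine field are removed and the affine part re-injected scaled by the
low-pass gain, so non-periodic gradients cannot leak wrap-around
harmonics into the rings while the all-gains-1 decomposition stays
exact. In blocked operation, chunks differ from the whole-volume result
only in the outermost slices, where the periodic wrap at the volume
boundary is approximated per chunk; block seams carry no excess error.

**Threshold.** The enhanced signal is two roughly zero-centered lobes
(background response vs structure response), so Otsu's criterion is
applied to the nonnegative lobe; the plain two-class split lands inside
the background lobe.

**Consolidation and caliber.** Thresholding a band-passed signal yields
speckle inside large structures and places boundaries one to two voxels
inside the true interface (each structure sits in the negative basin of
its own removed low frequencies). The segmentation therefore (i) grows
the thresholded mask into reference-bright voxels of the
pre-enhancement signal within a 2-voxel guard band per pass (the
enhanced image decides *what* is structure, the original grayscale
decides *where* its boundary lies), with the reference cut at the lower
quarter point between the Otsu class means — above background, yet
tolerant of tissue texture so inscribed balls keep their caliber; and
(ii) closes the result with a 6 µm ball before any connectivity logic.
Closing leaves convex tubes at their original caliber.

**Compartment logic.** The CSF is the largest 26-connected component of
the complement that does not touch the lateral faces (the SAS runs
axially through the section; peripheral porosity touches the sides).
Because the complement of the retained CSF is solid by construction, a
single Euclidean opening of it separates the wall bodies regardless of
interior speckle: the largest interior component is the ON, the
lateral-boundary components are the dural side. The complement of these
wall bodies is exactly the morphological closing of the CSF at the
opening radius (duality), so subtracting them from the thresholded
foreground — bounded to the CSF's 14 µm dilation reach — realizes the
"closing of the CSF intersected with the foreground" construction in a
form that is robust where a closing ball would interact with the domain
boundary. A one-voxel opening plus a 100 µm³ component filter removes
residual wall films and noise specks from the microstructure. Known
limitation (shared with any closing-based recipe): a few micrometres of
each trabecular junction cone are absorbed into the wall bodies, so
microstructure recall at the walls is below the mid-span recall
(≥ 95 %); thickness modes are unaffected because the tube mid-spans are
intact.

**Stitching.** Pairwise shifts come from Hann-windowed, whitened phase
correlation of the nominal overlaps, with the lowest-frequency octave
suppressed (robustness to per-tile background gradients) and a 3-point
parabolic sub-voxel refinement per axis. The Hann taper matters: crop
borders sit at identical positions in both crops and would otherwise
correlate coherently at zero lag. Global offsets solve the weighted
least-squares of pairwise shifts with tile 1 pinned. Blending estimates
one low-order polynomial background per tile by joint least squares on
overlap differences (a small ridge pins the gauge), subtracts them, and
feathers with separable raised-cosine ramps. On tiled phantoms the
recovered offsets are accurate to well under half a voxel and the
maximal cross-seam jump drops below 2 % of the naive mosaic's.

**Sector exclusion.** The damaged-sector discard is applied at
measurement time — voxels for volumes, triangles (by centroid azimuth)
for areas — rather than by zeroing masks, so the sector boundary
introduces no artificial cut faces into the surface area. Masks can
still be zeroed explicitly with `apply_sector_exclusion()` where a
truncated mask itself is wanted.

**Reported areas.** The interface area is reported twice: the total
CSF-boundary area (used for amplification factors) and the area
excluding the outermost, dura-facing boundary (triangles at the maximal
CSF radius), since published summaries do not disambiguate which is
meant.

## Problem sizes

The bundled validation runs on 96³–192³ phantoms at 1 µm voxels, 51³
digitized balls for volumetry/area checks, 24³–48³ grids for the
brute-force thickness oracle, and a two-chamber census phantom at 3 µm
voxels. These sizes exercise every code path, including blocked
enhancement, while keeping the whole suite at desk scale; the pipeline
itself is resolution-agnostic (all parameters are in µm).

## Known limitations

* The published study's headline numbers derive from terabyte-scale
  specimen data that are not redistributable; this package validates the
  *method* against analytic truth and checks the published summary
  arithmetic, not the specimen values themselves.
* Thin-sheet septae are segmented but not morphometrically
  distinguished from trabeculae.
* Amplification factors depend on segmentation caliber: a systematic
  half-voxel boundary bias changes a thin tube's area by ~10 % at the
  phantom's scales. The two-route amplification check (total mesh area
  vs per-component sums) guards arithmetic, not segmentation bias.
* The sector frame assumes the nerve axis is the z axis of the grid, as
  it is for tomographic sections cut across the nerve.
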