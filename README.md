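# sasmorph

Morphometry of the optic-nerve subarachnoid space (ON SAS) from 3D
grayscale tomography, at desk scale.

The SAS is the CSF-filled annulus between the optic nerve's pia and
arachnoid, bridged by trabeculae and septae that are lined by
meningothelial cells (MECs). Because MECs exchange material with the CSF,
the area of CSF-facing surface they cover matters physiologically. This
package implements the full measurement chain needed to quantify that
surface from micro-CT volumes:

* **tile registration and seamless stitching** — whitened (phase)
  correlation with sub-voxel refinement, least-squares offset
  reconciliation, joint per-tile background estimation and feathered
  blending;
* **curvelet-style enhancement** — a Fourier filter bank of dyadic radial
  rings × smooth angular wedges (default 4 octaves × 11 directions)
  forming a partition of unity; the low-pass band (smooth gradients) and
  the finest scales (noise, thin fixation filaments) are suppressed;
* **compartment segmentation** — hard threshold plus connectivity logic
  and Euclidean-ball morphology into three disjoint foregrounds: optic
  nerve (ON), SAS microstructure, CSF;
* **signed-distance geometry** — sub-voxel signed Euclidean distance
  field `φ` of the CSF; volume as the integral of a mollified step
  `U_ε(φ)`; interface area from a watertight zero level-set triangle
  mesh (marching tetrahedra);
* **maximal-inscribed-ball morphometry** — *trabecular thickness*
  `Th(v) = 2·max{ r : ∃ ball B(c,r) ⊆ foreground, v ∈ B }` on the
  microstructure; *trabecular separation* = the same measure on the CSF;
  volume-weighted density functions; a watershed census of
  intertrabecular fluid spaces above a diameter threshold;
* **summary report** — CSF volume and interface area with the
  microstructure in place and digitally removed; the **surface
  amplification factor** (area ratio) and the **microstructure volume
  fraction** `(V_empty − V_measured)/V_empty`, with angular
  renormalization `360/(360 − θ)` for a discarded damaged sector.

A seeded synthetic phantom — nerve cylinder, dural wall, trabeculated
CSF annulus with closed-form volume and area, tissue texture, membrane
linings, noise, gradients and fixation-like filaments — provides
analytic ground truth for every stage, including a brute-force
inscribed-ball oracle that the accelerated thickness path must match
voxel-exactly.

## Worked example

```r
library(sasmorph)

# a phantom nerve section: 192^3 voxels at 1 um, trabeculae of radius 6 um
spec <- phantom_spec(trabecula_radius_um_range = c(6, 6),
                     trabecula_count = 10, septum_count = 0, rng_seed = 11)
ph   <- generate_phantom(spec)

enh  <- enhance_volume(ph$volume)                 # band-pass enhancement
raw  <- threshold_segment(enh)                    # hard threshold (Otsu)
segs <- build_segments(raw, reference = ph$volume)
segs
#> <segment_set> ON 4.816e+05 um^3 | SAS microstructure 4.898e+04 um^3 | CSF 2.217e+06 um^3

th   <- local_thickness(segs$sas_mask, "sas")     # trabecular thickness
pdf  <- thickness_pdf(th, bin_width_um = 1)
pdf_mode(pdf)
#> [1] 11.5
```

The thickness density peaks at 11.5 µm — the 12 µm diameter of the
generating trabeculae, recovered through the whole imaging chain to
within the voxel-scale resolution of the measure. `compile_report(segs)`
then assembles volumes, interface areas, the amplification factor and
volume fraction; `tidy()`, `glance()` and `autoplot()` give tabular and
graphical summaries.

For the published reference measurements of two human ON SAS segments,

```r
reference_consistency()
#> # A tibble: 2 × 4
#>   dataset  segment      amplification_factor volume_fraction
#>   <chr>    <chr>                       <dbl>           <dbl>
#> 1 dataset1 bulbar                       4.86           0.365
#> 2 dataset2 intraorbital                 3.24           0.364
```

recomputes the surface amplification factors and microstructure volume
fractions from the printed areas and volumes.

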