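---
title: "Estimating below-canopy light regimes from airborne laser scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating below-canopy light regimes from airborne laser scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Light beneath forest canopies drives understory plant performance and
community assembly, but it is laborious to measure in the field and varies
strongly in space, especially on complex terrain. Hemispherical (fisheye)
photography is the classical point-based measurement: an upward-looking
image records which sky directions are blocked by foliage or terrain, and
radiation models turn that mask into light estimates. `canopylight`
synthesizes such images directly from airborne laser scanning (ALS) point
clouds and a digital terrain model, so the photographic survey can be
replaced by computation anywhere the lidar flew.

The pipeline has four layers:

1. **Geodata** — read classified LAS point clouds and terrain rasters;
   normalize return heights above a ground surface.
2. **Rendering** — transform returns to a camera-centered spherical frame
   and rasterize an equiangular fisheye occupancy image with
   distance-scaled markers, terrain-horizon masking (macro terrain), and
   ground returns above the camera (micro terrain).
3. **Light model** — canopy closure (solid-angle obscured fraction), a
   diffuse light index under the standard overcast sky, and a direct
   (beam) light index from growing-season sun tracking.
4. **Community analysis** — abundance-weighted light indicator values,
   Simpson turnover dissimilarity, and db-RDA variation partitioning of
   community turnover across light, macroclimate, and soil predictor
   groups.

A synthetic forest generator (terrain, conifer stands, communities along a
light gradient) provides inputs with known ground truth for every layer.

## Rendering model

Each return within 100 m of the camera is expressed as distance $r$,
elevation angle $\theta = \arcsin(\Delta z / r)$ and azimuth $\varphi$
(0 = North, clockwise). The image is an equiangular fisheye: radial pixel
distance is proportional to zenith angle, North up and East left (the view
looking up). Returns are printed as filled disks whose diameter falls
linearly with distance, 7 px for a return at the camera and 0.5 px at
100 m, anchored at a 1200-px reference image side. Because the markers are
calibrated against real photographs at that print size, their *angular*
size is held constant when other resolutions are rendered (diameters scale
with the image side).

True (non-normalized) coordinates are used, so canopy on an uphill slope
plots nearer the image center; ground returns above the camera darken the
image as micro-terrain; and every pixel below the terrain horizon computed
from a coarse (100-m) DTM — the maximum terrain elevation angle per 1°
azimuth bin, sampled at half-cell steps along each ray — is masked as
macro-terrain. Vegetation below the camera's horizontal plane cannot
obscure sky and is ignored.

### Boolean masks and fractional coverage

The rendered image stores *hard* boolean channels (canopy, macro-terrain,
micro-terrain): markers are stamped as hard disks and a sub-pixel marker
always sets the pixel containing its center, so occlusion is conservative
and deterministic. Hard sub-pixel stamping, however, inflates the obscured
area as the pixel grid coarsens. The renderer therefore also accumulates a
fractional *coverage* channel: each marker deposits its exact disk area
(sub-pixel case) or an area-exact anti-aliased disk (larger markers; the
linear edge ramp integrates to $\pi r^2 + \pi/12$, so the effective radius
is shrunk accordingly), composed across markers as a probabilistic union
$c \leftarrow c + a(1 - c)$. The radiometric integrals below use this
coverage channel; masks, PNG export and set-level properties use the
boolean channels. With this split, the light indices computed at 600 px
and 2,400 px agree to within about 0.002 on synthetic stands spanning
stem densities of 50-600/ha, well inside the 0.01 convergence target we
test; with hard booleans alone the closure bias at 600 px was about 0.01
on dense stands.

## Light model

**Canopy closure** is the solid-angle-weighted obscured fraction of the
hemisphere. For equiangular pixels the solid angle per pixel is
proportional to $\sin\zeta / \zeta$ (zenith angle $\zeta$); the center
pixel takes the limit value 1.

**Diffuse light index (DLI).** Sky radiance follows the standard overcast
sky, $L(\zeta)/L_Z = (1 + b\cos\zeta)/(1+b)$ with gradation $b = 1$. The
index is the ratio of SOC irradiance on a horizontal sensor through the
visible sky to the fully open-sky value,
$\sum_\text{visible} L\cos\zeta\,\omega \big/ \sum_\text{all}
L\cos\zeta\,\omega$. Because the SOC shape is time-invariant, the seasonal
ratio collapses to this single spatial integral — no time quadrature is
needed. For a sky open only within a cap of half-angle $\theta_h$ around
the zenith the index has the closed form
$1 - (3\cos^2\theta_h + 2\cos^3\theta_h)/5$, which the tests verify at
four horizon heights to ±0.005.

**Direct (beam) light index (BLI).** The sun is tracked across the growing
season (May 1 - September 30) in 10-minute steps of true solar time.
Declination uses the Spencer Fourier series; the tests hold elevations to
within 0.5° of an independent Meeus-style ephemeris over 1,000 random
latitude/day/time draws. Each time step contributes a horizontal-surface
beam weight $w = \tau^{m}\sin e$ with $\tau = 0.40$ at sea level and
Kasten-Young air mass $m$ scaled by the barometric ratio
$e^{-\text{alt}/8434\,\text{m}}$; the extraterrestrial constant cancels in
the index. The solar disk (angular radius 0.266°) is sampled with a fixed
19-point pattern, so even sub-pixel disks are supersampled, and the index
is $\sum_t w_t v_t / \sum_t w_t$ with $v_t$ the visible disk fraction.
The open reference is the fully open sky at the same latitude and
altitude, horizontal sensor; terrain masking belongs to the site mask, not
to the reference. The diffuse fraction parameter (20%) does not enter
either ratio index and is retained only for absolute-irradiance output.
Longitude and equation-of-time corrections are deliberately omitted: in
true solar time they cancel from a seasonal integral parameterized by
latitude and altitude only.

## Area-based canopy cover and plot aggregation

Canopy cover is computed from the height-normalized cloud: per 4-m cell,
the proportion of first returns that are vegetation higher than 1 m above
ground among all first returns. Ground normalization uses a moving plane —
the least-squares plane through the 12 nearest ground returns of each
position. We first implemented the classical Delaunay-TIN interpolation,
but the triangulation packages available to us needed minutes per
million-return stand; the moving plane is exact on planar ground, exact at
ground-return positions, translation-invariant, and runs in seconds via a
k-d tree, which is why we adopted it.

Plot-level values follow the field protocol the package targets: circular
200-m² plots; cover aggregated over the 4-m raster pixels whose centers
fall inside the plot; light indices sampled by 16 cameras on a 4-m mesh
whose centroid coincides with the plot center (offsets ±2 and ±6 m — the
anchoring is our choice; the protocol fixes only mesh and count), at 1 m
above ground. Summaries are means and standard deviations of natural-log
values (log base only rescales regression slopes, not R²). Index values of
0 — possible under a fully closed canopy — are floored at $10^{-3}$ before
the log and flagged; the choice is ours, made once.

The plot orchestration computes the terrain horizon once per plot (at the
plot center) rather than per camera: across a 12-m camera grid the horizon
from a 100-m DTM is effectively constant.

## Community analysis

The community layer follows standard vegetation-survey practice.
Braun-Blanquet classes convert to percent cover by the midpoint table
r = 0.1, + = 0.5, 1 = 2.5, 2 = 15 (2a = 10, 2b = 20.5), 3 = 37.5,
4 = 62.5, 5 = 87.5; the community light indicator is the cover-weighted
mean of species light values (species without a value are excluded from
numerator and denominator). Turnover uses the Simpson pairwise
dissimilarity $\beta_{sim} = \min(b,c)/(a + \min(b,c))$ on
presence/absence, which is zero for nested communities.

db-RDA is delegated to `vegan::capscale`: principal coordinates of the
dissimilarity matrix, redundancy analysis of the real axes on the
covariates. Negative eigenvalues are dropped (no Lingoes/Cailliez
correction) and R² denominators use the positive-eigenvalue inertia only.
Adjusted R² is Ezekiel's $1 - (1 - R^2)(n-1)/(n-p-1)$ with $p$ the number
of *retained* covariate columns — collinear columns are dropped with a
warning and do not count toward $p$, which keeps the exact identity that a
duplicated predictor group has zero independent fraction. Variation
partitioning fits the seven group unions and solves the
inclusion-exclusion system exactly, so the raw fractions plus residual sum
to 1 by construction; the reporting view floors negative fractions at
zero (they indicate a group explaining less than random covariates
would), while raw values are retained.

## The synthetic forest generator

The generator emulates the study conditions the method targets: conifer
stands scanned at ≥ 10 returns/m² on sloping terrain with surrounding
ridges, and plant communities whose species turn over along a light
gradient.

* **Terrain**: a planar slope plus Gaussian ridges (linear crests at a
  given azimuth, distance, height and width), on a 100-m grid.
* **Stands**: Poisson-placed stems; cone crowns (the conifer archetype)
  filled uniformly with vegetation returns at 1.5 points/m³ of crown;
  ground returns uniform at 4 points/m². With moderate stocking this
  exceeds the 10 returns/m² condition (a 300 stems/ha default stand runs
  at about 15/m²). First-return flags go to the highest return of each
  0.5-m planimetric column — a simplification of pulse geometry that is
  adequate for count-ratio metrics.
* **Communities**: Gaussian niches on a (0,1] light gradient (default
  breadth 0.15, pool of 30 species), lognormal abundance noise (σ = 0.3),
  quantized through the Braun-Blanquet scale and back, with a 0.05%
  detection floor; species light values increase with the niche optimum.
  Covariate tables provide a noisy light group, a climate group with a
  configurable light correlation, and an independent soil group.

What the generator does *not* emulate: occlusion (returns are sampled from
crown volumes regardless of what lies above), multi-return pulse physics,
leaf-on/leaf-off differences, crown shapes other than cones, and species
co-occurrence structure beyond the niche model. Passing tests therefore
demonstrate the internal consistency and analytic correctness of the
pipeline, not its agreement with field photographs.

## Numerical choices and test problem sizes

* Image side defaults to 1,200 px; convergence is verified between 600
  and 2,400 px (tolerance 0.01; observed ≤ 0.002).
* Horizon profile: 360 azimuth bins, rays sampled at half-cell steps to
  the grid edge, angles floored at 0.
* Sun tracking: 10-minute steps by default; bulk tests use 30-60 minutes,
  which changes the index by far less than the tolerances tested.
* Solid-angle weights use the exact equiangular Jacobian
  $\sin\zeta/\zeta$; the center pixel uses the limit value.
* Ground surface: 12 nearest ground returns; degenerate (collinear)
  neighborhoods fall back to the nearest ground elevation; clouds with
  fewer than 3 non-collinear ground returns are rejected.
* Tests run on stands of roughly 0.6-4.4 ha at 10-15 returns/m²
  (10⁵-10⁶ returns), 43-plot communities with 30 species, and 50
  simulation replicates for the variation-partitioning recovery — sizes
  chosen to exercise every code path at full fidelity while keeping the
  default suite fast.

## Known limitations

* LAS 1.1-1.4 point formats 0-5 are read; LAZ compression is not.
* Terrain rasters use the ESRI ASCII grid format.
* No radiometric realism: no return intensity, transmittance, or leaf
  optics; markers are opaque disks.
* The direct index ignores circumsolar brightening and refraction; the
  diffuse index assumes the SOC shape regardless of season.
* Sensors are horizontal; slope-parallel irradiance is out of scope.
* db-RDA significance testing (permutation) is not implemented; the
  package reports variance fractions only.
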