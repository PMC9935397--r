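---
title: "Leaflet-resolved analysis of membrane nanotubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaflet-resolved analysis of membrane nanotubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafletscope)
```

## The problem

Highly curved membrane nanotubes -- here, bilayer tubes of roughly 40 Å
lumen diameter constricted inside a helical ESCRT-III-type protein coat --
are too small for conventional membrane-composition assays, and their two
leaflets experience radically different curvature. `leafletscope`
implements the two complementary quantification routes for such systems:

1. **Coarse-grained simulation analysis**: given bead coordinates of a
   lipid tubule (Martini-style resolution) and the positions of the
   membrane-inserted phenylalanine anchors of the protein coat, resolve the
   bilayer into inner/outer leaflets and angular zones, and compute radial
   bead densities, headgroup surface density maps, tail tilt-angle
   distributions, per-zone molar compositions, leaflet thicknesses, and
   lateral diffusion coefficients.
2. **Cryo-EM map analysis**: given 3D density maps of reconstructions in
   which one lipid species at a time carries brominated tails (2 Br per
   double bond), quantify per-leaflet lipid composition from the excess
   scattering of each brominated species, and leaflet thicknesses from a
   three-Gaussian fit of the radial scattering profile.

A synthetic-data generator produces ground-truth tubules, trajectories, and
voxelized maps with the same statistical structure, so every stage is
testable by parameter recovery without any external data.

## Geometry and leaflet assignment

The tubule axis is assumed straight and parallel to z within a frame (the
protein coat is rigid). The in-plane center $(x_0,y_0)$ is fit by
least-squares circle regression on the anchor points: minimize
$\sum_i \left(\lVert a_i - c\rVert - \bar r(c)\right)^2$ by Gauss--Newton
from the anchor centroid (`fit_tubule_center()`). For anchors forming a
regular polygon the solution coincides with the centroid; the fit is exact
on noiseless circles and agrees with a brute-force grid search on noisy
ones (see the test suite).

Leaflets are assigned by **single-linkage agglomerative clustering** of the
phospholipid phosphate-bead coordinates, cut at exactly two clusters
(`stats::hclust`, `assign_leaflets()`). On a tubule the two leaflets are
concentric point shells separated by the hydrophobic core, which single
linkage separates unambiguously *provided the shells are denser than the
gap*: with the default 1,300 lipids the nearest-neighbour spacing within a
leaflet (~7 Å) is far below the ~20 Å inter-leaflet gap. Sparse tubules
(a few hundred lipids) can chain-break; the function warns when the
cluster size ratio exceeds 50:1. Sterols, which lack a phosphate, inherit
the leaflet of the nearest phosphate to their hydroxyl bead, with exact
ties broken toward the smaller lipid id (`assign_cholesterol()`).

Angular **zones** partition the surface relative to the protein: the
*contact* zone is the 30° wedge (half-width 15°) centered on the
phenylalanine contact azimuth, the *gap* zone the 30° wedge 180° across,
the rest *other*. Because the anchors form a helix, the contact azimuth is
a function of height: `anchor_helix_fit()` unwraps anchor azimuth against
z and fits a line ($\theta_c(z)$, slope = 360°/pitch, ~7.06°/Å at 17
subunits per turn and 3 Å rise), robust to missing subunits. Whether the
wedges co-rotate with the helix or are fixed per z-slab is configurable
(`follow_helix`, default `TRUE` -- a fixed wedge would cut across the
helical stripe that the contact sites actually trace on the surface).
Lipids are assigned to zones by their phosphate bead; compositions gather
*all* non-headgroup beads by each bead's own position (see below).

## Simulation observables

**Radial density profiles** (`radial_density_profile()`): Gaussian KDE of
bead radii, bandwidth 0.5 Å, evaluated from 0 to 80 Å at 0.2 Å spacing;
the per-bin mass is divided by the annulus area $2\pi r\,\Delta r$ (the
$\Delta r$ cancels against the KDE bin mass) and scaled by the bead count,
so $\int \rho(r)\, 2\pi r\, dr$ returns the selected bead count up to
kernel truncation at the grid bounds (conservation is asserted to 1% in
the tests; no renormalization of truncated mass is applied). The r = 0
point is set to zero (zero-area annulus).

**Headgroup surface maps** (`headgroup_density_map()`): 2D Gaussian KDE of
headgroup reference beads (NC3/CNO/C1) on the unrolled $(\theta, z)$
surface, grid fixed at 1° × 0.835 Å. Points within 15% of each border are
mirrored outward before estimation and the estimate is evaluated on the
untrimmed grid only, bounding edge artifacts below 1%; mirrored copies
carry reflected mass of the same points, so the density is normalized by
the *unexpanded* point count. Replicates are averaged, then the map is
min-max normalized to [0, 1]. The default bandwidths are **(2.5°, 0.5 Å)**
rather than a data-driven rule: surface features co-rotate with the steep
anchor helix, so any z-smoothing $b_z$ smears azimuth by
$(360°/\mathrm{pitch})\, b_z \approx 7 b_z$; keeping $b_z$ below one grid
spacing holds the effective azimuthal resolution near 4°. Silverman's rule
(available via `bw = NULL`) assumes a smooth near-Gaussian field and
over-smooths the near-uniform azimuth axis by an order of magnitude,
erasing the 30°-wide helical furrow entirely -- it remains appropriate
only when the surface is believed featureless.

**Tilt angles** (`tilt_angles()`, `tilt_distribution()`): per tail, the
vector from the phosphate bead to the tail's last bead, measured against
$+\hat r$ for the inner leaflet and $-\hat r$ for the outer, so 0° is
membrane-normal in both leaflets and the distributions are exactly
invariant under turning the tubule inside-out. Distributions are Gaussian
KDEs on 0--180° with 0.05° bandwidth and 0.9° grid spacing. Two numerical
consequences of that (deliberately narrow) bandwidth are handled
explicitly: (i) each gridded replicate density is renormalized to unit
trapezoid integral before replicate averaging, so the integral invariant
holds at any sample size; (ii) the distribution mode is *not* the raw grid
argmax (which lands on shot-noise spikes) but a local quadratic fit of the
raw density over a ±9° window centered on a 9-bin moving average of the
curve. Replicates are normalized first and averaged afterwards.

**Zone compositions** (`zone_composition()`): every non-headgroup bead is
gathered by its own $(\theta, z)$ zone and its lipid's leaflet; bead
counts are divided by each species' whole-lipid non-headgroup bead count
(SDPC 12, POPS 11, CHOL 8, PIP2 11) to give lipid equivalents, and
normalized to 100 mol% within each (leaflet, zone). Headgroups are
excluded from the divisor because PIP2's five-bead headgroup would
otherwise overweight it (one bead for SDPC/POPS). Empty zones yield
flagged `NaN` rows rather than errors.

**Leaflet thickness** (`leaflet_thickness_sim()`): the glycerol plane of
each leaflet is the density-weighted mean radius of its glycerol-bead
profile; the bilayer midplane is the radius between the glycerol planes
where the inner- and outer-leaflet terminal-tail densities cross --- tails
of opposing leaflets meet at the physical midplane, and a density-based
estimator matches the rest of the module. Thicknesses are the
glycerol-to-midplane distances. When the tail densities do not cross, a
structured error carrying both profiles is raised.

**Lateral diffusion** (`lateral_diffusion()`): per lipid the azimuth is
unwrapped over time and motion mapped to surface coordinates
$(\bar R\,\theta, z)$; the MSD is averaged over lipids and all time
origins at ~20 lags spanning 10--50% of the trajectory, and
$D = \mathrm{slope}/4$ from a through-origin least-squares fit. Lipids
that change leaflet would be excluded; the Brownian generator never flips
them.

## The synthetic generator

`tubule_spec()`/`generate_tubule_snapshot()` place phosphate beads on two
concentric cylinders (defaults: inner 25 Å, outer 45 Å reference radii --
a ~40 Å lumen and ~40 Å bilayer), with an anchor helix of 17 subunits per
turn at 55 Å radius and 3 Å rise, 1,300 lipids in a 58.2:18:17.5:6.3
SDPC:CHOL:POPS:PIP2 mixture split between leaflets in proportion to
leaflet radius. Species counts follow the requested fractions *exactly*
via largest-remainder rounding, so recovery tests are deterministic in the
counts. Tails extend toward the midplane at a von Mises tilt (defaults:
inner mean 25°, outer 15°, concentration 33 ≈ 10° spread -- inner-leaflet
tails must tilt more to fill the smaller luminal volume); every bead gets
0.75 Å Gaussian jitter, a typical coarse-grained thermal positional
spread. The optional **furrow** models the hydrophobic defect scored into
the outer leaflet along the anchor helix: no polar headgroup may reside
inside the stripe, so exclusion acts on realized (post-jitter) headgroup
positions, displacing offenders 5° past the stripe edge (the steric arc of
a displaced headgroup at the outer radius); a configurable fraction of
affected lipids have their sn-2 terminal bead placed radially outside the
anchor radius ("backflipping"). Trajectories are surface Brownian motion
with per-leaflet D (wrapping azimuth, reflecting tube ends) -- the
analysis assumes only diffusive in-leaflet motion, not Martini physics.

`map_spec()`/`generate_density_map()` build maps as cylindrical Gaussian
shells: positive headgroup shells at 30 and 47.2 Å (width 2.2 Å), a
negative aliphatic trough at 36.8 Å (width 2.8 Å) -- i.e. a built-in
peak-to-trough asymmetry of 3.6 Å, inner leaflet thinner -- plus a protein
shell at 58 Å, optional azimuthal contact-site modulation following the
helix, per-species bromine shells proportional to ground-truth leaflet
mol fraction × Br count (unit amplitude 0.15, keeping the contrast
perturbative relative to the trough depth), and voxel Gaussian noise.
Shell widths are kept near 2--3 Å so the three-Gaussian decomposition of
the summed profile stays well-conditioned, as it must have been for the
real reconstructions; with 3--3.5 Å widths the components blend and the
nine-parameter fit becomes degenerate.

What the generator does **not** emulate: lipid conformational detail
(beads are placed on straight tail vectors), membrane elasticity and
undulations, leaflet flip-flop, protein structure (anchors are points),
CTF effects, and map anisotropy. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated statistical
model, not robustness to every artifact of real cryo-EM maps or Martini
trajectories.

## EM quantification

Maps are normalized so the solvent plateau (mean radial intensity over the
outermost 10% of usable radii -- the paper-style definition of solvent as
zero does not state an estimator, so a plateau average is used) maps to 0
and the mean radial intensity in the protein shell window maps to 1
(`normalize_map_to_protein()`); the whole pipeline is exactly invariant to
gain and offset of the input maps. For contact-site-resolved analysis each
z slice is rotated by $-(\mathrm{twist}/\mathrm{rise})(z - z_\mathrm{ref})$
about the tubule center with bilinear interpolation
(`align_slices_by_contact_sites()`, reference: central slice), making the
contact azimuth z-independent; bulk analysis omits this step. The central
30% of slices is projected (`central_projection()`), radially averaged
with ring sampling (`radial_average()`), and the reference (unbrominated)
profile is fit with $A_1 G - A_2 G + A_3 G$ (amplitudes positive,
initialized from the windowed argmax/argmin/argmax; Levenberg--Marquardt
via `minpack.lm`). The trough center $\mu_2$ defines the leaflet split;
thicknesses are $\mu_2 - \mu_1$ and $\mu_3 - \mu_2$. The default fit
window (20--52 Å) spans the membrane annulus between lumen and protein
shell -- the protein tail must stay outside the window or it biases the
outer-peak component.

`leaflet_areas()` integrates $\max(v, 0)$ by trapezoid from the zero
crossing below the inner peak to the split, and from the split to the zero
crossing above the outer peak (zero-crossing bounds keep lumen and protein
intensity out; fixed-radius bounds are not used since the profile shape
already defines the membrane support). `bromine_composition()` subtracts
reference areas from each brominated map's areas per leaflet, divides by
Br atoms per molecule (defaults SDPC 12, POPS 2, CHOL 2, PIP2 4 -- nominal
full bromination, overridable when measured bromination is known), clamps
negative excesses to zero with a warning, and normalizes to 100 mol% per
leaflet. With half maps the entire analysis runs per half and reports the
between-half mean and standard deviation (`halfmap_uncertainty()`).

## Problem sizes and numerical tolerances used in the tests

The recovery suite runs at the study scale the generator defaults define:
1,300-lipid tubules (10 seeds for leaflet assignment, 3 replicates for
compositions, 10 replicates for tilt -- the replicate count of the
simulated system the tilt analysis emulates), 96×96×48 maps at 1.5 Å
voxels (20 seeds at 5% voxel noise for thickness), and 500 lipids × 2,000
frames for diffusion. Diffusion tests use a 1,020 nm tube: nanotubes are
micron-scale in vitro, and at the default 102 Å test length the reflecting
ends truncate the MSD inside the lag window and bias D low by several
percent. Key asserted tolerances: leaflet assignment exact; center fit
mean error < 0.5 Å at 1 Å anchor jitter and < 1e-3 Å from a brute-force
grid oracle; compositions within 2 mol% of the generator's bead-level
ground truth with closure to 100 ± 0.01; tilt mode within 2°, densities
integrating to 1 ± 1e-3, inside-out mirror exact; furrow in-stripe mean
below half the out-of-stripe mean; EM thickness asymmetry within 0.3 Å of
the built-in 3.6 Å at 5% noise; EM compositions within 2 mol% noise-free
and 5 mol% at 5% noise; diffusion within 10%; KDE count conservation
within 1%.

## Known limitations

- Single-linkage leaflet assignment needs leaflet point density higher
  than the inter-leaflet gap; very sparse or porous tubules break it (a
  warning fires, but no fallback clustering is attempted).
- The tubule axis is assumed straight per frame; flexing tubules would
  need a curved-axis generalization.
- The three-Gaussian thickness model requires resolvable headgroup peaks;
  heavily blended profiles (peak widths comparable to leaflet separation)
  make the decomposition ill-conditioned and the fit window choice
  material.
- Bromine excess areas respond slightly nonlinearly when the added
  contrast is large enough to lift the clipped trough region above zero;
  compositions are accurate in the perturbative-contrast regime the
  method assumes.
- The diffusion estimator assumes in-leaflet Brownian motion with stable
  leaflet labels; subdiffusive or hop-diffusing lipids would bias the
  through-origin slope.
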