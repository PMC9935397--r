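# leafletscope

Leaflet-resolved structural and compositional analysis of highly curved
lipid membrane nanotubes.

Membrane nanotubes constricted inside helical protein coats (ESCRT-III
type CHMP1B/IST1 filaments) have a lumen of only ~40 Å and two leaflets
under radically different curvature. This package implements the two
quantification routes for such systems and the synthetic ground truth to
validate them:

- **Coarse-grained simulation analysis.** From bead coordinates of a lipid
  tubule plus the membrane-inserted phenylalanine anchor positions of the
  coat: leaflet assignment by single-linkage clustering of phosphate beads
  (cut at two clusters; sterols join the nearest phosphate's leaflet),
  least-squares circle fit of the tubule axis, cylindrical coordinates,
  30° contact/gap wedges following the anchor helix, radial bead-density
  profiles (Gaussian KDE, bandwidth 0.5 Å, normalized by 2πrΔr), headgroup
  surface density maps on a 1° × 0.835 Å grid with 15% mirror padding,
  tail tilt-angle distributions against the signed radial normal (0° =
  membrane-normal in both leaflets), per-zone molar compositions from
  non-headgroup bead counts (divisors: SDPC 12, POPS 11, CHOL 8, PIP2 11),
  leaflet thicknesses from glycerol planes and the terminal-tail density
  crossing, and per-leaflet lateral diffusion from MSD slopes (D =
  slope/4).
- **Cryo-EM map analysis with halogenated-lipid probes.** From MRC/CCP4
  maps of reconstructions where one species at a time carries brominated
  tails: protein-intensity normalization with zero solvent, optional
  per-slice rotational alignment of the helical contact sites, central 30%
  z projection, radial averaging, a three-Gaussian fit
  A₁G(μ₁,σ₁) − A₂G(μ₂,σ₂) + A₃G(μ₃,σ₃) of the unbrominated profile giving
  leaflet thicknesses μ₂−μ₁ and μ₃−μ₂, leaflet areas above solvent between
  zero crossings, and bromine-difference compositions: excess(s, leaflet) =
  area_s − area_ref, normalized by Br atoms per molecule and scaled to
  100 mol% per leaflet, with half-map standard deviations.
- **Synthetic generator.** Ground-truth tubule snapshots (concentric
  leaflet cylinders, helical anchor lattice with 17 subunits/turn,
  largest-remainder species counts, von Mises tail tilts, optional helical
  headgroup-exclusion furrow with sn-2 backflipping), Brownian surface
  trajectories, and voxelized Gaussian-shell density maps with per-species
  bromine contrast and noise.

See the vignette (`vignettes/nanotube-leaflet-analysis.Rmd`) for the
models, parameter choices, and numerical details.

## Worked example

```r
library(leafletscope)
templates <- default_lipid_templates()

# a 1,300-lipid ground-truth tubule with the standard four-lipid mixture
spec <- tubule_spec(seed = 7)
snap <- generate_tubule_snapshot(spec, templates)

center <- fit_tubule_center(snap$anchors)
labels <- assign_cholesterol(snap,
                             assign_leaflets(snap, templates, center),
                             templates)
table(labels$leaflet)
#> inner outer
#>   464   836

coords <- to_cylindrical(snap, center)
comp <- zone_composition(coords, labels, snap$anchors, zone_spec(),
                         templates)
subset(comp, zone == "contact",
       c(leaflet, species, bead_count, lipid_equivalents, molar_percent))
#>    leaflet species bead_count lipid_equivalents molar_percent
#> 1    inner    CHOL         69              8.62         17.43
#> 2    inner    PIP2         23              2.09          4.23
#> 3    inner    POPS         91              8.27         16.72
#> 4    inner    SDPC        366             30.50         61.63
#> 13   outer    CHOL        103             12.88         18.64
#> 14   outer    PIP2         66              6.00          8.69
#> 15   outer    POPS        112             10.18         14.74
#> 16   outer    SDPC        480             40.00         57.92
```

The bead counts are whole-lipid equivalents (e.g. 366 SDPC beads / 12
non-headgroup beads per SDPC = 30.5 lipids) and the molar percentages
close to 100 within each (leaflet, zone): at this seed the contact wedge
of the inner leaflet holds 61.6 mol% SDPC against the 58.2 mol% global
mixture.

Leaflet thickness from a synthetic cryo-EM map with 5% voxel noise:

```r
m <- generate_density_map(map_spec(noise_sigma = 0.05), seed = 7)
mn <- normalize_map_to_protein(m, protein_r_range = c(53, 63))
fit <- fit_three_gaussians(radial_average(mn), window = c(20, 52))
sprintf("thickness inner %.2f A, outer %.2f A, asymmetry %.2f A",
        fit$thickness_inner, fit$thickness_outer, fit$asymmetry)
#> "thickness inner 6.84 A, outer 10.36 A, asymmetry 3.53 A"
```

The generator builds its shells with a 3.6 Å inner-vs-outer peak-to-trough
asymmetry (the thinner concave leaflet of a highly curved bilayer); the
end-to-end pipeline recovers it to within a tenth of an Ångström here.

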