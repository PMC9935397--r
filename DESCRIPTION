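Package: leafletscope
Title: Leaflet-Resolved Structural Analysis of Lipid Membrane Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Zone- and leaflet-resolved structural and compositional analysis
    of highly curved lipid membrane nanotubes. Provides leaflet assignment by
    single-linkage clustering of phosphate beads, least-squares tubule axis
    fitting, cylindrical radial density profiles and tilt-angle distributions
    from coarse-grained bead coordinates, per-zone molar compositions, lateral
    diffusion estimation, and quantification of per-leaflet lipid composition
    and leaflet thickness from cryo-EM density maps using halogenated-lipid
    contrast probes. Includes a synthetic-data generator producing
    ground-truth tubule snapshots, trajectories, and voxelized density maps
    so every analysis stage is testable by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
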