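# minimal two-species templates for hand-built geometry fixtures
simple_templates <- function() {
  list(
    PL = lipid_template("PL", phosphate_bead = "PO4",
                        headgroup_beads = "NC3",
                        tail_terminal_beads = c("T1", "T2"),
                        glycerol_beads = "GL1",
                        all_beads = c("NC3", "PO4", "GL1", "T1", "T2"),
                        head_reference_bead = "NC3",
                        br_atoms_per_molecule = 2),
    ST = lipid_template("ST", phosphate_bead = "ROH",
                        headgroup_beads = character(),
                        tail_terminal_beads = "R2",
                        glycerol_beads = character(),
                        all_beads = c("ROH", "R1", "R2"),
                        br_atoms_per_molecule = 2)
  )
}

# two concentric cylinders of single-bead "phosphate" lipids; one bead per
# lipid is enough for clustering/zone fixtures
cylinder_phosphates <- function(n_per_leaflet, r_inner = 25, r_outer = 45,
                                length = 100, jitter = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  id <- 0L
  for (lf in c(inner = r_inner, outer = r_outer)) {
    th <- runif(n_per_leaflet, 0, 2 * pi)
    zz <- runif(n_per_leaflet, 0, length)
    x <- lf * cos(th) + rnorm(n_per_leaflet, 0, jitter)
    y <- lf * sin(th) + rnorm(n_per_leaflet, 0, jitter)
    z <- zz + rnorm(n_per_leaflet, 0, jitter)
    rows[[length(rows) + 1L]] <- data.frame(
      species = "PL", lipid_id = id + seq_len(n_per_leaflet), bead = "PO4",
      x = x, y = y, z = z,
      true_leaflet = names(which(c(inner = r_inner, outer = r_outer) == lf)))
    id <- id + n_per_leaflet
  }
  do.call(rbind, rows)
}

# a full PL lipid built bead-by-bead at a given phosphate position with the
# tail along `dir` (unit vector); used for tilt-convention fixtures
pl_lipid <- function(lipid_id, p0, dir, head_dir = -dir, tail_len = 9) {
  data.frame(
    species = "PL", lipid_id = lipid_id,
    bead = c("NC3", "PO4", "GL1", "T1", "T2"),
    x = p0[1] + c(head_dir[1] * 2, 0, dir[1] * 2, dir[1] * tail_len,
                  dir[1] * tail_len),
    y = p0[2] + c(head_dir[2] * 2, 0, dir[2] * 2, dir[2] * tail_len,
                  dir[2] * tail_len),
    z = p0[3] + c(head_dir[3] * 2, 0, dir[3] * 2, dir[3] * tail_len,
                  dir[3] * tail_len))
}

trapz_num <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# anchors on a perfect helix (for zone fixtures without a full tubule spec)
helix_anchors <- function(n = 34, radius = 55, rise = 3,
                          subunits_per_turn = 17, center = c(0, 0)) {
  k <- seq_len(n) - 1
  th <- k * 2 * pi / subunits_per_turn
  data.frame(subunit = k + 1L,
             x = center[1] + radius * cos(th),
             y = center[2] + radius * sin(th),
             z = k * rise)
}
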