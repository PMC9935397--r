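#' Specification of a synthetic ground-truth tubule
#'
#' Describes the geometry and statistics of a two-leaflet cylindrical lipid
#' nanotube with a helical lattice of protein anchor points. Defaults match
#' the system the analysis targets: a ~40 Angstrom lumen (inner reference
#' radius 25 A), a ~40 A bilayer (outer reference radius 45 A), an anchor
#' helix of 17 subunits per turn at 55 A, and 1,300 lipids in a
#' 58.2:18:17.5:6.3 SDPC:CHOL:POPS:PIP2 molar mixture.
#'
#' @param r_inner,r_outer Reference-bead (phosphate) radii of the inner and
#'   outer leaflets, Angstrom.
#' @param tube_length Tubule length along z, Angstrom.
#' @param fractions_inner,fractions_outer Named per-leaflet species molar
#'   fractions; each must sum to 1.
#' @param n_lipids_total Total lipid count (split between leaflets in
#'   proportion to leaflet radius).
#' @param subunits_per_turn,rise_per_subunit Helical lattice of anchors.
#' @param anchor_radius Radius of the anchor helix, Angstrom.
#' @param axis_offset `(x0, y0)` displacement of the tubule axis.
#' @param noise_sigma Gaussian positional jitter applied to every bead,
#'   Angstrom.
#' @param tilt Per-leaflet tail tilt model: list with `mean_inner`,
#'   `mean_outer` (degrees from the leaflet normal) and `kappa`
#'   (von Mises concentration).
#' @param tail_length_inner,tail_length_outer Phosphate-to-terminal tail
#'   length per leaflet, Angstrom.
#' @param furrow `NULL`, or a list with `halfwidth_deg` (azimuthal stripe
#'   half-width about the anchor helix), `backflip_fraction` (fraction of
#'   affected lipids whose sn-2 terminal bead is displaced radially outside
#'   the anchor radius), and optional `halfwidth_z`.
#' @param seed Integer seed; every random draw derives from it.
#' @return Object of class `tubule_spec`.
#' @export
tubule_spec <- function(r_inner = 25, r_outer = 45, tube_length = 102,
                        fractions_inner = c(SDPC = 0.582, CHOL = 0.18,
                                            POPS = 0.175, PIP2 = 0.063),
                        fractions_outer = fractions_inner,
                        n_lipids_total = 1300L,
                        subunits_per_turn = 17L, rise_per_subunit = 3.0,
                        anchor_radius = 55, axis_offset = c(0, 0),
                        noise_sigma = 0.75,
                        tilt = list(mean_inner = 25, mean_outer = 15,
                                    kappa = 33),
                        tail_length_inner = 9, tail_length_outer = 9,
                        furrow = NULL, seed = 1L) {
  if (!(r_inner > 0 && r_inner < r_outer)) stop("need 0 < r_inner < r_outer")
  if (n_lipids_total < 10L) stop("n_lipids_total must be >= 10")
  for (fr in list(fractions_inner, fractions_outer))
    if (abs(sum(fr) - 1) > 1e-9) stop("leaflet fractions must sum to 1")
  if (!is.null(furrow)) {
    if (is.null(furrow$halfwidth_deg) && !is.null(furrow$halfwidth_z))
      furrow$halfwidth_deg <- NA_real_  # resolved from helix slope later
    if (!is.null(furrow$halfwidth_deg) && !is.na(furrow$halfwidth_deg) &&
        furrow$halfwidth_deg < 0)
      stop("furrow halfwidth must be >= 0")
    if (is.null(furrow$backflip_fraction)) furrow$backflip_fraction <- 0
  }
  if (r_outer - r_inner < max(tail_length_inner, tail_length_outer))
    stop("leaflet separation smaller than tail length")
  structure(list(r_inner = r_inner, r_outer = r_outer,
                 tube_length = tube_length,
                 fractions_inner = fractions_inner,
                 fractions_outer = fractions_outer,
                 n_lipids_total = as.integer(n_lipids_total),
                 subunits_per_turn = as.integer(subunits_per_turn),
                 rise_per_subunit = rise_per_subunit,
                 anchor_radius = anchor_radius,
                 axis_offset = as.numeric(axis_offset),
                 noise_sigma = noise_sigma, tilt = tilt,
                 tail_length_inner = tail_length_inner,
                 tail_length_outer = tail_length_outer,
                 furrow = furrow, seed = as.integer(seed)),
            class = "tubule_spec")
}

#' Largest-remainder apportionment of species counts
#'
#' Deterministically converts molar fractions into integer counts summing
#' exactly to `n`: floor each quota, then hand the remaining units to the
#' largest fractional remainders (ties to earlier species).
#'
#' @param fractions Named numeric fractions summing to 1.
#' @param n Total count.
#' @return Named integer vector summing to `n`.
#' @export
largest_remainder_counts <- function(fractions, n) {
  quota <- fractions * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate the helical anchor lattice of a tubule spec
#'
#' Anchors are placed at radius `anchor_radius`, azimuth
#' `k * 360 / subunits_per_turn` and height `k * rise_per_subunit`
#' (k = 0, 1, ...), offset by `axis_offset`; the count is
#' `floor(tube_length / rise_per_subunit)`.
#'
#' @param spec A [tubule_spec()].
#' @return data.frame with `subunit`, `x`, `y`, `z`.
#' @export
generate_anchor_helix <- function(spec) {
  if (spec$rise_per_subunit <= 0) stop("rise_per_subunit must be > 0")
  if (spec$subunits_per_turn < 3L) stop("need >= 3 subunits per turn")
  n <- floor(spec$tube_length / spec$rise_per_subunit)
  if (n < spec$subunits_per_turn)
    stop("tube_length must cover at least one helical turn")
  k <- seq_len(n) - 1
  th <- k * 2 * pi / spec$subunits_per_turn
  data.frame(subunit = as.integer(k + 1L),
             x = spec$axis_offset[1] + spec$anchor_radius * cos(th),
             y = spec$axis_offset[2] + spec$anchor_radius * sin(th),
             z = k * spec$rise_per_subunit)
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy envelope)
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Generate a ground-truth tubule snapshot
#'
#' Builds a two-leaflet cylindrical snapshot realizing a [tubule_spec()]:
#' per-leaflet species counts follow the spec fractions exactly (largest
#' remainder rounding); phosphate (reference) beads sit at the leaflet
#' radius; tails extend toward the bilayer midplane at a tilt angle drawn
#' from the per-leaflet von Mises tilt model; headgroups sit just beyond
#' the phosphate on the polar side; Gaussian jitter `noise_sigma` is added
#' to every bead. With a furrow enabled, outer-leaflet lipids whose
#' phosphate azimuth falls within the helical stripe have their headgroup
#' beads displaced to the stripe edge and a `backflip_fraction` of them
#' have the sn-2 terminal bead moved radially outside the anchor radius.
#'
#' @param spec A [tubule_spec()].
#' @param templates Named list of [lipid_template()]s.
#' @return A [tubule_snapshot()] with attribute `ground_truth`: a
#'   data.frame (`lipid_id`, `species`, `leaflet`, `zone`, `tilt_deg`,
#'   `in_furrow`, `backflipped`).
#' @export
generate_tubule_snapshot <- function(spec, templates = default_lipid_templates()) {
  set.seed(spec$seed)
  anchors <- generate_anchor_helix(spec)
  helix_slope <- 360 / (spec$subunits_per_turn * spec$rise_per_subunit)
  theta_c <- function(z) (z * helix_slope) %% 360

  n_outer <- round(spec$n_lipids_total * spec$r_outer /
                     (spec$r_inner + spec$r_outer))
  n_inner <- spec$n_lipids_total - n_outer
  counts <- list(inner = largest_remainder_counts(spec$fractions_inner, n_inner),
                 outer = largest_remainder_counts(spec$fractions_outer, n_outer))

  furrow <- spec$furrow
  if (!is.null(furrow) && (is.null(furrow$halfwidth_deg) ||
                           is.na(furrow$halfwidth_deg)))
    furrow$halfwidth_deg <- furrow$halfwidth_z * helix_slope

  beads_list <- list()
  gt_list <- list()
  lipid_id <- 0L
  for (leaflet in c("inner", "outer")) {
    R0 <- if (leaflet == "inner") spec$r_inner else spec$r_outer
    Ltail <- if (leaflet == "inner") spec$tail_length_inner
             else spec$tail_length_outer
    tilt_mean <- if (leaflet == "inner") spec$tilt$mean_inner
                 else spec$tilt$mean_outer
    sgn <- if (leaflet == "inner") 1 else -1   # tails point toward midplane
    for (sp in names(counts[[leaflet]])) {
      nsp <- counts[[leaflet]][[sp]]
      if (nsp == 0L) next
      tpl <- template_for(templates, sp)
      for (j in seq_len(nsp)) {
        lipid_id <- lipid_id + 1L
        th <- stats::runif(1, 0, 360)
        zz <- stats::runif(1, 0, spec$tube_length)
        tilt <- abs(rvonmises(1, tilt_mean * pi / 180, spec$tilt$kappa)) * 180 / pi
        rhat <- c(cos(th * pi / 180), sin(th * pi / 180), 0)
        that <- c(-rhat[2], rhat[1], 0)
        zhat <- c(0, 0, 1)
        nhat <- sgn * rhat                       # leaflet normal (tailward)
        phi <- stats::runif(1, 0, 2 * pi)
        ehat <- cos(phi) * that + sin(phi) * zhat
        dhat <- cos(tilt * pi / 180) * nhat + sin(tilt * pi / 180) * ehat
        p0 <- R0 * rhat + c(0, 0, zz)

        lab <- character(0); pos <- NULL
        addb <- function(labels, points) {
          lab <<- c(lab, labels)
          pos <<- rbind(pos, points)
        }
        addb(tpl$phosphate_bead, matrix(p0, 1))
        hg <- setdiff(tpl$headgroup_beads, tpl$phosphate_bead)
        if (length(hg))
          addb(hg, t(vapply(seq_along(hg), function(k)
            p0 - nhat * (1.5 + 0.5 * (k - 1)), numeric(3))))
        if (length(tpl$glycerol_beads))
          addb(tpl$glycerol_beads, t(vapply(seq_along(tpl$glycerol_beads),
            function(k) p0 + dhat * (1.0 + 0.8 * (k - 1)), numeric(3))))
        # tail beads: evenly spaced along dhat out to Ltail at each terminal
        placed <- c(tpl$phosphate_bead, hg, tpl$glycerol_beads)
        tails <- tail_bead_chains(tpl)
        for (ti in seq_along(tails)) {
          chain <- tails[[ti]]
          nb <- length(chain)
          frac <- seq_len(nb) / nb
          addb(chain, t(vapply(frac, function(f) p0 + dhat * (f * Ltail),
                               numeric(3))))
          placed <- c(placed, chain)
        }
        rest <- setdiff(tpl$all_beads, placed)
        if (length(rest))  # any remaining beads ride midway down the tail
          addb(rest, t(vapply(seq_along(rest), function(k)
            p0 + dhat * (0.5 * Ltail + 0.3 * k), numeric(3))))

        pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$noise_sigma),
                            nrow(pos), 3)

        in_fur <- FALSE; backflip <- FALSE
        if (!is.null(furrow) && leaflet == "outer") {
          # the furrow is a hydrophobic defect: no polar headgroup may
          # reside inside the helical stripe, so exclusion acts on the
          # realized (jittered) headgroup positions. Displaced beads land
          # just past the stripe edge; the 5 deg margin is the steric
          # footprint of a displaced headgroup (~4 A arc at the outer
          # leaflet radius).
          head_idx <- which(lab %in% tpl$headgroup_beads)
          for (k in head_idx) {
            th_k <- (atan2(pos[k, 2], pos[k, 1]) * 180 / pi) %% 360
            tc_k <- theta_c(pos[k, 3])
            d_k <- circ_dist_deg(th_k, tc_k)
            if (d_k > furrow$halfwidth_deg) next
            in_fur <- TRUE
            shift <- furrow$halfwidth_deg + 5 - d_k
            sgn_th <- if (((th_k - tc_k) %% 360) < 180) 1 else -1
            rot <- sgn_th * shift * pi / 180
            pos[k, 1:2] <- c(pos[k, 1] * cos(rot) - pos[k, 2] * sin(rot),
                             pos[k, 1] * sin(rot) + pos[k, 2] * cos(rot))
          }
          if (in_fur && stats::runif(1) < furrow$backflip_fraction &&
              length(tpl$tail_terminal_beads) >= 2L) {
            backflip <- TRUE
            sn2 <- tpl$tail_terminal_beads[2]
            k <- which(lab == sn2)
            rad_out <- spec$anchor_radius + 2 + abs(stats::rnorm(1))
            pos[k, ] <- rad_out * rhat + c(0, 0, zz)
          }
        }
        # ground-truth zone follows the realized phosphate bead position
        kph <- which(lab == tpl$phosphate_bead)[1]
        th_ph <- (atan2(pos[kph, 2], pos[kph, 1]) * 180 / pi) %% 360
        z_ph <- pos[kph, 3]
        pos[, 1] <- pos[, 1] + spec$axis_offset[1]
        pos[, 2] <- pos[, 2] + spec$axis_offset[2]
        beads_list[[lipid_id]] <- data.frame(
          species = sp, lipid_id = lipid_id, bead = lab,
          x = pos[, 1], y = pos[, 2], z = pos[, 3])
        dcon <- circ_dist_deg(th_ph, theta_c(z_ph))
        dgap <- circ_dist_deg(th_ph, theta_c(z_ph) + 180)
        zone <- if (dcon <= 15) "contact" else if (dgap <= 15) "gap" else "other"
        gt_list[[lipid_id]] <- data.frame(
          lipid_id = lipid_id, species = sp, leaflet = leaflet, zone = zone,
          tilt_deg = tilt, theta = th, z0 = zz,
          edge_dist_deg = min(abs(dcon - 15), abs(dgap - 15)),
          in_furrow = in_fur, backflipped = backflip)
      }
    }
  }
  beads <- do.call(rbind, beads_list)
  gt <- do.call(rbind, gt_list)
  half_box <- max(spec$anchor_radius + 20, 80)
  snap <- tubule_snapshot(beads, anchors,
                          box = c(2 * half_box, 2 * half_box,
                                  max(spec$tube_length, 10)),
                          frame = 0L)
  attr(snap, "ground_truth") <- gt
  attr(snap, "spec") <- spec
  snap
}

# split the tail beads of a template into per-tail chains ending at each
# terminal bead, using the trailing letter convention (C1A..C4A / C1B..D5B)
tail_bead_chains <- function(tpl) {
  core <- setdiff(tpl$all_beads,
                  c(tpl$headgroup_beads, tpl$phosphate_bead,
                    tpl$glycerol_beads))
  if (length(tpl$tail_terminal_beads) == 1L) {
    # sterols: single chain of all ring/tail beads, terminal last
    term <- tpl$tail_terminal_beads
    return(list(c(setdiff(core, term), term)))
  }
  lapply(tpl$tail_terminal_beads, function(term) {
    suffix <- substring(term, nchar(term))
    chain <- core[substring(core, nchar(core)) == suffix]
    if (!term %in% chain) chain <- c(chain, term)
    # order so the terminal bead comes last
    c(setdiff(chain, term), term)
  })
}

#' Generate a Brownian surface trajectory from a tubule spec
#'
#' Each lipid performs 2D Brownian motion on its leaflet cylinder: per
#' frame, displacements in the surface coordinates `(R * theta, z)` are
#' drawn independently as Normal(0, sqrt(2 D dt)) per coordinate, with
#' per-leaflet diffusion coefficients. Azimuth wraps; z reflects at the
#' tube ends.
#'
#' @param spec A [tubule_spec()].
#' @param n_frames Number of frames (>= 2).
#' @param D Named vector `c(inner = , outer = )` of diffusion coefficients
#'   in Angstrom^2/ns (a single value applies to both leaflets).
#' @param frame_dt Frame interval in ns.
#' @param templates Templates used to lay out the initial snapshot.
#' @return Object of class `tubule_trajectory`: lipid table (with leaflet
#'   and radius), `theta` and `z` matrices `[frame, lipid]`, `dt`, and the
#'   initial snapshot.
#' @export
generate_trajectory <- function(spec, n_frames, D = c(inner = 1, outer = 1),
                                frame_dt = 1,
                                templates = default_lipid_templates()) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (length(D) == 1L) D <- c(inner = unname(D), outer = unname(D))
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  snap <- generate_tubule_snapshot(spec, templates)
  gt <- attr(snap, "ground_truth")
  n <- nrow(gt)
  R <- ifelse(gt$leaflet == "inner", spec$r_inner, spec$r_outer)
  sig <- sqrt(2 * D[gt$leaflet] * frame_dt)
  theta <- matrix(0, n_frames, n)
  zpos <- matrix(0, n_frames, n)
  theta[1, ] <- gt$theta
  zpos[1, ] <- gt$z0
  L <- spec$tube_length
  for (f in 2:n_frames) {
    darc <- stats::rnorm(n, 0, sig)
    dz <- stats::rnorm(n, 0, sig)
    theta[f, ] <- (theta[f - 1, ] + darc / R * 180 / pi) %% 360
    znew <- zpos[f - 1, ] + dz
    # reflect at the tube ends
    znew <- abs(znew)
    znew <- L - abs(L - znew)
    zpos[f, ] <- znew
  }
  structure(list(lipids = data.frame(lipid_id = gt$lipid_id,
                                     species = gt$species,
                                     leaflet = gt$leaflet, radius = R),
                 theta = theta, z = zpos, dt = frame_dt,
                 snapshot = snap, spec = spec),
            class = "tubule_trajectory")
}

#' Reconstruct a full snapshot for one trajectory frame
#'
#' Rigidly translates each lipid of the base snapshot to its frame
#' position on the cylinder surface (rotation about the axis plus z
#' shift).
#'
#' @param traj A `tubule_trajectory`.
#' @param frame Frame index (1-based).
#' @return A [tubule_snapshot()].
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= nrow(traj$theta))
  snap <- traj$snapshot
  gt <- attr(snap, "ground_truth")
  b <- snap$beads
  off <- traj$spec$axis_offset
  idx <- match(b$lipid_id, gt$lipid_id)
  dth <- (traj$theta[frame, idx] - gt$theta[idx]) * pi / 180
  dz <- traj$z[frame, idx] - gt$z0[idx]
  x0 <- b$x - off[1]; y0 <- b$y - off[2]
  b$x <- off[1] + x0 * cos(dth) - y0 * sin(dth)
  b$y <- off[2] + x0 * sin(dth) + y0 * cos(dth)
  b$z <- b$z + dz
  out <- tubule_snapshot(b, snap$anchors, snap$box, frame = as.integer(frame))
  attr(out, "ground_truth") <- gt
  out
}
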