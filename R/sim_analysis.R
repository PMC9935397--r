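#' Radial bead density profile
#'
#' Gaussian kernel density estimate of the cylindrical radii of a bead
#' selection, evaluated on a uniform radial grid and converted to a
#' surface-density-like profile: the per-bin KDE mass is divided by the
#' annulus area `2 pi r dr` (the `dr` factors cancel) and scaled by the
#' number of selected beads, so that integrating `value * 2 pi r dr` over
#' the grid recovers the selected bead count (up to kernel truncation at
#' the grid bounds). The value at r = 0 is set to 0 (zero-area annulus).
#'
#' @param coords Cylindrical bead coordinates from [to_cylindrical()].
#' @param select Logical vector (or `NULL` for all rows) choosing the
#'   beads to profile.
#' @param bw KDE bandwidth, Angstrom (default 0.5).
#' @param r_max Upper grid bound, Angstrom (default 80).
#' @param dr Grid spacing, Angstrom (default 0.2).
#' @param label Provenance label for the profile.
#' @return A [radial_profile()]; attribute `n_beads` records the
#'   selection size. An empty selection yields an all-zero profile with a
#'   warning.
#' @export
radial_density_profile <- function(coords, select = NULL, bw = 0.5,
                                   r_max = 80, dr = 0.2, label = "") {
  r <- if (is.null(select)) coords$r else coords$r[select]
  grid <- seq(0, r_max, by = dr)
  if (!length(r)) {
    warning("empty bead selection; returning all-zero profile")
    prof <- radial_profile(grid, rep(0, length(grid)), label = label)
    attr(prof, "n_beads") <- 0L
    return(prof)
  }
  kde <- stats::density(r, bw = bw, kernel = "gaussian",
                        from = 0, to = r_max, n = length(grid))
  val <- length(r) * kde$y / (2 * pi * grid)
  val[1] <- 0
  prof <- radial_profile(grid, val, label = label)
  attr(prof, "n_beads") <- length(r)
  prof
}

#' Select beads of a snapshot's cylindrical coordinates by role
#'
#' Builds the logical selection vectors used with
#' [radial_density_profile()]: filters by species, bead role
#' (`"phosphate"`, `"headgroup"`, `"glycerol"`, `"tail_terminal"`,
#' `"nonheadgroup"`, `"all"` or explicit bead labels), leaflet and zone.
#'
#' @param coords Cylindrical coordinates with `species`, `lipid_id`,
#'   `bead` columns.
#' @param templates Named list of [lipid_template()]s.
#' @param species Species subset (`NULL` = all).
#' @param role Bead role or explicit labels.
#' @param leaflet `"inner"`, `"outer"` or `NULL`; requires `labels`.
#' @param zone `"contact"`, `"gap"`, `"other"` or `NULL`; requires `zones`.
#' @param labels Leaflet labels (from [assign_leaflets()] /
#'   [assign_cholesterol()]).
#' @param zones Zone labels (from [assign_zones()]).
#' @return Logical vector over rows of `coords`.
#' @export
select_beads <- function(coords, templates, species = NULL, role = "all",
                         leaflet = NULL, zone = NULL, labels = NULL,
                         zones = NULL) {
  keep <- rep(TRUE, nrow(coords))
  if (!is.null(species)) keep <- keep & coords$species %in% species
  role_beads <- function(tpl) {
    switch(role[1],
           all = tpl$all_beads,
           phosphate = tpl$phosphate_bead,
           headgroup = tpl$headgroup_beads,
           glycerol = tpl$glycerol_beads,
           tail_terminal = tpl$tail_terminal_beads,
           nonheadgroup = tpl$nonheadgroup_beads,
           role)
  }
  ok <- rep(FALSE, nrow(coords))
  for (sp in unique(coords$species)) {
    tpl <- template_for(templates, sp)
    ok <- ok | (coords$species == sp & coords$bead %in% role_beads(tpl))
  }
  keep <- keep & ok
  if (!is.null(leaflet)) {
    if (is.null(labels)) stop("leaflet filter requires labels")
    ids <- labels$lipid_id[labels$leaflet == leaflet]
    keep <- keep & coords$lipid_id %in% ids
  }
  if (!is.null(zone)) {
    if (is.null(zones)) stop("zone filter requires zones")
    ids <- zones$lipid_id[zones$zone == zone]
    keep <- keep & coords$lipid_id %in% ids
  }
  keep
}

# separable 2D Gaussian KDE of points (px, py) on a rectangular grid;
# n_norm is the unexpanded point count (mirror copies carry reflected
# mass of the same points and must not deflate the density)
kde2d_grid <- function(px, py, gx, gy, bwx, bwy, n_norm = length(px)) {
  Kx <- outer(gx, px, function(g, p) stats::dnorm(g - p, sd = bwx))
  Ky <- outer(py, gy, function(p, g) stats::dnorm(g - p, sd = bwy))
  (Kx %*% Ky) / n_norm
}

#' Headgroup surface density map
#'
#' 2D Gaussian KDE of headgroup reference bead positions on the unrolled
#' tubule surface (theta, z), with mirror padding: points within
#' `mirror_frac` of each border (in theta and z) are reflected outward
#' before the KDE is computed, and the estimate is evaluated on the
#' untrimmed grid only, suppressing edge artifacts. Grids are fixed at
#' 1 degree in theta and 0.835 Angstrom in z. Multiple frames/replicates
#' (a list of coordinate tables) are averaged before the final min-max
#' normalization to [0, 1].
#'
#' @param coords Cylindrical coordinates, or a list of them (frames).
#' @param labels Leaflet labels (single table, or list matching `coords`).
#' @param templates Named list of [lipid_template()]s.
#' @param species Species subset (default: all with a headgroup).
#' @param leaflet Leaflet analyzed (default `"outer"`).
#' @param z_range Length-2 z interval; default spans the selected points.
#' @param bw Length-2 bandwidths (theta deg, z Angstrom). Default
#'   `c(2.5, 0.5)`: features on the tubule surface follow the steep
#'   anchor helix (~7 degrees of azimuth per Angstrom of z), so any z
#'   smoothing smears azimuth by `slope * bw_z`; the z bandwidth is
#'   therefore kept below one grid spacing, giving an effective azimuthal
#'   resolution of ~4 degrees. Pass `NULL` for Silverman's rule per axis
#'   (appropriate for smooth, near-uniform surfaces, but it over-smooths
#'   helical features by an order of magnitude).
#' @param theta_spacing,z_spacing Grid spacings (1 deg, 0.835 A).
#' @param mirror_frac Border fraction mirrored (default 0.15).
#' @return List of class `surface_density_map`: `theta` grid, `z` grid,
#'   `values` matrix (theta x z) normalized to [0, 1], `bw`, `n_points`.
#' @export
headgroup_density_map <- function(coords, labels, templates,
                                  species = NULL, leaflet = "outer",
                                  z_range = NULL, bw = c(2.5, 0.5),
                                  theta_spacing = 1, z_spacing = 0.835,
                                  mirror_frac = 0.15) {
  frames <- if (is.data.frame(coords)) list(coords) else coords
  lab_list <- if (is.data.frame(labels)) rep(list(labels), length(frames))
              else labels
  pts <- lapply(seq_along(frames), function(i) {
    co <- frames[[i]]
    keep <- rep(FALSE, nrow(co))
    for (sp in unique(co$species)) {
      tpl <- template_for(templates, sp)
      if (is.na(tpl$head_reference_bead)) next
      if (!is.null(species) && !sp %in% species) next
      keep <- keep | (co$species == sp & co$bead == tpl$head_reference_bead)
    }
    ids <- lab_list[[i]]$lipid_id[lab_list[[i]]$leaflet == leaflet]
    keep <- keep & co$lipid_id %in% ids
    co[keep, c("theta", "z")]
  })
  all_pts <- do.call(rbind, pts)
  if (nrow(all_pts) < 10L)
    warning("fewer than 10 headgroup points; map will be noisy")
  if (is.null(z_range)) z_range <- range(all_pts$z)
  gth <- seq(0, 360 - theta_spacing, by = theta_spacing)
  nzg <- max(2L, floor(diff(z_range) / z_spacing) + 1L)
  gz <- z_range[1] + (seq_len(nzg) - 1) * z_spacing

  expand <- function(p) {
    th <- p$theta; z <- p$z
    tpad <- 360 * mirror_frac
    zpad <- diff(z_range) * mirror_frac
    th_m <- c(th,
              -th[th <= tpad],                 # mirror about theta = 0
              720 - th[th >= 360 - tpad])      # mirror about theta = 360
    z_m <- c(z,
             z[th <= tpad],
             z[th >= 360 - tpad])
    lo <- z_m <= z_range[1] + zpad
    hi <- z_m >= z_range[2] - zpad
    data.frame(theta = c(th_m, th_m[lo], th_m[hi]),
               z = c(z_m, 2 * z_range[1] - z_m[lo], 2 * z_range[2] - z_m[hi]))
  }
  if (is.null(bw)) {
    exp_all <- expand(all_pts)
    bw <- c(stats::bw.nrd0(exp_all$theta), stats::bw.nrd0(exp_all$z))
  }

  acc <- matrix(0, length(gth), length(gz))
  for (p in pts) {
    if (!nrow(p)) next
    e <- expand(p)
    acc <- acc + kde2d_grid(e$theta, e$z, gth, gz, bw[1], bw[2],
                            n_norm = nrow(p))
  }
  acc <- acc / length(frames)
  rng <- range(acc)
  values <- if (rng[2] > rng[1]) (acc - rng[1]) / (rng[2] - rng[1])
            else acc
  structure(list(theta = gth, z = gz, values = values, bw = bw,
                 n_points = nrow(all_pts), raw_range = rng),
            class = "surface_density_map")
}

#' Per-tail lipid tilt angles
#'
#' For every phospholipid, the orientation vector of each tail runs from
#' the phosphate bead to the tail's last bead; the tilt angle is measured
#' against the signed radial direction (+r for the inner leaflet, -r for
#' the outer), so 0 degrees means membrane-normal in both leaflets.
#' Sterols are excluded; zero-length tail vectors are skipped (count
#' recorded in attribute `n_skipped`).
#'
#' @param snapshot A [tubule_snapshot()].
#' @param labels Leaflet labels covering the phospholipids.
#' @param zones Zone labels from [assign_zones()].
#' @param center Tubule center `(x0, y0)`.
#' @param templates Named list of [lipid_template()]s.
#' @return data.frame `lipid_id`, `species`, `tail` (1-based index),
#'   `leaflet`, `zone`, `angle` (degrees in [0, 180]).
#' @export
tilt_angles <- function(snapshot, labels, zones, center,
                        templates = default_lipid_templates()) {
  b <- snapshot$beads
  out <- list()
  skipped <- 0L
  for (sp in unique(b$species)) {
    tpl <- template_for(templates, sp)
    if (is_sterol(tpl)) next
    sub <- b[b$species == sp, ]
    ph <- sub[sub$bead == tpl$phosphate_bead, ]
    ph <- ph[order(ph$lipid_id), ]
    for (ti in seq_along(tpl$tail_terminal_beads)) {
      tb <- sub[sub$bead == tpl$tail_terminal_beads[ti], ]
      tb <- tb[order(tb$lipid_id), ]
      stopifnot(identical(ph$lipid_id, tb$lipid_id))
      vx <- tb$x - ph$x; vy <- tb$y - ph$y; vz <- tb$z - ph$z
      nrm <- sqrt(vx^2 + vy^2 + vz^2)
      rr <- sqrt((ph$x - center[1])^2 + (ph$y - center[2])^2)
      rhx <- (ph$x - center[1]) / rr
      rhy <- (ph$y - center[2]) / rr
      lf <- labels$leaflet[match(ph$lipid_id, labels$lipid_id)]
      sgn <- ifelse(lf == "inner", 1, -1)
      cosang <- (vx * rhx + vy * rhy) * sgn / nrm
      ok <- nrm > 1e-9
      skipped <- skipped + sum(!ok)
      ang <- acos(pmin(1, pmax(-1, cosang[ok]))) * 180 / pi
      out[[length(out) + 1L]] <- data.frame(
        lipid_id = ph$lipid_id[ok], species = sp, tail = ti,
        leaflet = lf[ok],
        zone = zones$zone[match(ph$lipid_id[ok], zones$lipid_id)],
        angle = ang)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- skipped
  res
}

#' Tilt-angle distributions per (species, tail, leaflet, zone)
#'
#' Gaussian KDE of tilt angles on a 0-180 degree grid (0.9 degree
#' spacing, bandwidth 0.05 degrees by default). Each replicate (element of
#' a list of [tilt_angles()] tables) is estimated and renormalized to unit
#' trapezoid integral on the grid before averaging across replicates, so
#' the averaged density also integrates to 1.
#'
#' @param angles A [tilt_angles()] table or a list of them (replicates).
#' @param bw KDE bandwidth in degrees (default 0.05).
#' @param grid_spacing Grid spacing in degrees (default 0.9).
#' @return data.frame `species`, `tail`, `leaflet`, `zone`, `angle`,
#'   `density`, `mean_angle` (per-group mean of the raw angles),
#'   `mode_angle` (quadratic-refined density peak).
#' @export
tilt_distribution <- function(angles, bw = 0.05, grid_spacing = 0.9) {
  reps <- if (is.data.frame(angles)) list(angles) else angles
  grid <- seq(0, 180, by = grid_spacing)
  all_ang <- do.call(rbind, reps)
  groups <- unique(all_ang[, c("species", "tail", "leaflet", "zone")])
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    dens_acc <- rep(0, length(grid))
    nrep <- 0L
    vals_all <- numeric(0)
    for (rep_df in reps) {
      sel <- rep_df$species == g$species & rep_df$tail == g$tail &
        rep_df$leaflet == g$leaflet & rep_df$zone == g$zone
      v <- rep_df$angle[sel]
      if (!length(v)) next
      vals_all <- c(vals_all, v)
      d <- stats::density(v, bw = bw, from = 0, to = 180, n = length(grid))$y
      integ <- trapz(grid, d)
      if (integ > 0) d <- d / integ
      dens_acc <- dens_acc + d
      nrep <- nrep + 1L
    }
    if (nrep == 0L) next
    dens <- dens_acc / nrep
    out[[length(out) + 1L]] <- data.frame(
      species = g$species, tail = g$tail, leaflet = g$leaflet,
      zone = g$zone, angle = grid, density = dens,
      mean_angle = mean(vals_all),
      mode_angle = peak_location(grid, dens, window = 7.2))
  }
  do.call(rbind, out)
}

#' @keywords internal
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

# peak location of a gridded curve: a short moving average locates the
# peak region (the raw argmax of an undersampled, spiky KDE can sit on a
# shot-noise spike), then a local quadratic fit of the raw curve around
# that center refines the position
peak_location <- function(x, y, window = 9) {
  ma <- stats::filter(y, rep(1 / 9, 9), sides = 2)
  ma[is.na(ma)] <- 0
  i0 <- which.max(ma)
  sel <- abs(x - x[i0]) <= window
  if (sum(sel) < 5L) return(x[i0])
  fit <- stats::lm.fit(cbind(1, x[sel], x[sel]^2), y[sel])
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(x[which.max(y)])
  peak <- -b[2] / (2 * b[3])
  if (peak < min(x[sel]) || peak > max(x[sel])) x[which.max(y)]
  else unname(peak)
}

#' Per-leaflet, per-zone molar composition
#'
#' Gathers every non-headgroup bead, assigns it to a zone by its own
#' (theta, z) position and to its lipid's leaflet, and converts bead
#' counts to lipid equivalents using each species' non-headgroup bead
#' count as divisor. Molar percentages are normalized to 100 within each
#' (leaflet, zone). Zones with zero beads yield `NaN` percentages and a
#' `flag`.
#'
#' @param coords Cylindrical coordinates from [to_cylindrical()].
#' @param labels Leaflet labels covering every lipid (sterols included).
#' @param anchors Anchor table (for the helical zone centerline).
#' @param spec A [zone_spec()].
#' @param templates Named list of [lipid_template()]s.
#' @return data.frame `leaflet`, `zone`, `species`, `bead_count`,
#'   `lipid_equivalents`, `molar_percent`, `flag`.
#' @export
zone_composition <- function(coords, labels, anchors, spec = zone_spec(),
                             templates = default_lipid_templates()) {
  keep <- rep(FALSE, nrow(coords))
  div <- numeric(nrow(coords))
  for (sp in unique(coords$species)) {
    tpl <- template_for(templates, sp)
    sel <- coords$species == sp & coords$bead %in% tpl$nonheadgroup_beads
    keep <- keep | sel
    div[sel] <- tpl$nonheadgroup_bead_count
  }
  co <- coords[keep, ]
  div <- div[keep]
  center <- attr(coords, "center")
  bead_zone <- zone_of_points(co$theta, co$z, anchors, center, spec)
  lf <- labels$leaflet[match(co$lipid_id, labels$lipid_id)]
  if (anyNA(lf)) stop("leaflet labels missing for some lipids")
  species_all <- sort(unique(coords$species))
  out <- list()
  for (leaflet in c("inner", "outer")) for (zone in c("contact", "gap", "other")) {
    sel <- lf == leaflet & bead_zone == zone
    cnt <- table(factor(co$species[sel], levels = species_all))
    eq <- as.numeric(cnt) /
      vapply(species_all, function(s)
        template_for(templates, s)$nonheadgroup_bead_count, numeric(1))
    tot <- sum(eq)
    out[[length(out) + 1L]] <- data.frame(
      leaflet = leaflet, zone = zone, species = species_all,
      bead_count = as.integer(cnt), lipid_equivalents = eq,
      molar_percent = if (tot > 0) 100 * eq / tot else NaN,
      flag = if (tot > 0) "" else "empty_zone")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Leaflet thicknesses from simulation radial densities
#'
#' The glycerol plane of each leaflet is the density-weighted mean radius
#' of its glycerol-bead profile (weights `value * 2 pi r`); the bilayer
#' midplane is the radius between the two glycerol planes where the
#' inner- and outer-leaflet terminal-tail densities cross. Thicknesses
#' are `r_mid - r_glycerol_inner` and `r_glycerol_outer - r_mid`.
#'
#' @param glycerol_inner,glycerol_outer Glycerol-bead
#'   [radial_density_profile()]s per leaflet.
#' @param tails_inner,tails_outer Terminal-tail-bead profiles per leaflet.
#' @return List `r_glycerol_inner`, `r_glycerol_outer`, `r_mid`,
#'   `thickness_inner`, `thickness_outer`, `thickness_bilayer`.
#' @export
leaflet_thickness_sim <- function(glycerol_inner, glycerol_outer,
                                  tails_inner, tails_outer) {
  wmean_r <- function(p) {
    w <- p$value * 2 * pi * p$r
    sum(p$r * w) / sum(w)
  }
  rg_in <- wmean_r(glycerol_inner)
  rg_out <- wmean_r(glycerol_outer)
  if (!(rg_in < rg_out)) stop("inner glycerol plane not inside outer plane")
  stopifnot(identical(tails_inner$r, tails_outer$r))
  r <- tails_inner$r
  dif <- tails_inner$value - tails_outer$value
  win <- which(r > rg_in & r < rg_out)
  sgn <- sign(dif[win])
  cross <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  if (!length(cross)) {
    err <- structure(
      list(message = "no terminal-tail density crossing between the glycerol planes",
           call = sys.call(-1),
           profiles = list(tails_inner = tails_inner,
                           tails_outer = tails_outer)),
      class = c("leafletscope_no_crossing", "error", "condition"))
    stop(err)
  }
  i <- win[cross[1]]
  r_mid <- r[i] + (r[i + 1] - r[i]) * dif[i] / (dif[i] - dif[i + 1])
  list(r_glycerol_inner = rg_in, r_glycerol_outer = rg_out, r_mid = r_mid,
       thickness_inner = r_mid - rg_in, thickness_outer = rg_out - r_mid,
       thickness_bilayer = rg_out - rg_in)
}

#' Per-leaflet lateral diffusion coefficient from a surface trajectory
#'
#' Unwraps each lipid's azimuth over time, converts motion to surface
#' displacements `(R * dtheta, dz)` with `R` the lipid's mean radius,
#' accumulates the mean squared displacement over all lipids and time
#' origins at a set of lag times, and fits `MSD = 4 D tau` by least
#' squares over a lag window (default 10-50% of the trajectory length).
#'
#' @param traj A `tubule_trajectory` (from [generate_trajectory()] or
#'   built with the same fields: `lipids$leaflet`, `lipids$radius`,
#'   matrices `theta`, `z` `[frame, lipid]`, `dt`).
#' @param lag_window Fractions of the trajectory length bounding the lag
#'   fit window.
#' @param n_lags Number of lag samples in the window.
#' @return List per leaflet: `D` (Angstrom^2/ns), plus a `msd` table
#'   (`leaflet`, `tau_ns`, `msd`).
#' @export
lateral_diffusion <- function(traj, lag_window = c(0.1, 0.5), n_lags = 20L) {
  nf <- nrow(traj$theta)
  if (nf < 50L) stop("need >= 50 frames for diffusion estimation")
  lags <- unique(pmax(1L, round(seq(lag_window[1] * nf, lag_window[2] * nf,
                                    length.out = n_lags))))
  th_un <- apply(traj$theta, 2, function(v) {
    d <- diff(v)
    d <- d - 360 * round(d / 360)
    cumsum(c(v[1], d))
  })
  res <- list(msd = NULL, D = c())
  msd_rows <- list()
  Dv <- c()
  for (lf in unique(traj$lipids$leaflet)) {
    sel <- traj$lipids$leaflet == lf
    R <- traj$lipids$radius[sel]
    arc <- sweep(th_un[, sel, drop = FALSE] * pi / 180, 2, R, "*")
    zz <- traj$z[, sel, drop = FALSE]
    msd <- vapply(lags, function(L) {
      da <- arc[(L + 1):nf, , drop = FALSE] - arc[1:(nf - L), , drop = FALSE]
      dz <- zz[(L + 1):nf, , drop = FALSE] - zz[1:(nf - L), , drop = FALSE]
      mean(da^2 + dz^2)
    }, numeric(1))
    tau <- lags * traj$dt
    slope <- sum(tau * msd) / sum(tau^2)   # through-origin least squares
    Dv[lf] <- slope / 4
    msd_rows[[lf]] <- data.frame(leaflet = lf, tau_ns = tau, msd = msd)
  }
  list(D = Dv, msd = do.call(rbind, msd_rows))
}

#' Pointwise mean and standard deviation across replicates
#'
#' Averages congruent result tables (or profiles) cellwise: numeric value
#' columns get `mean` and sample `sd` (n - 1 denominator); key columns
#' must be identical across replicates. A single replicate yields
#' `sd = NaN` and a flag attribute.
#'
#' @param results List of congruent data.frames.
#' @param value_cols Names of numeric columns to average (default: all
#'   numeric columns not shared-identical across replicates is
#'   impractical, so all numeric columns are averaged).
#' @return data.frame: key columns, then `<col>_mean` and `<col>_sd`.
#' @export
average_replicates <- function(results, value_cols = NULL) {
  stopifnot(length(results) >= 1L)
  ref <- results[[1L]]
  if (is.null(value_cols))
    value_cols <- names(ref)[vapply(ref, is.numeric, logical(1))]
  key_cols <- setdiff(names(ref), value_cols)
  for (r in results[-1L]) {
    if (!identical(dim(r), dim(ref)) ||
        !identical(r[key_cols], ref[key_cols]))
      stop("replicates have mismatched grids/keys")
  }
  out <- ref[key_cols]
  n <- length(results)
  for (vc in value_cols) {
    mat <- vapply(results, function(r) as.numeric(r[[vc]]),
                  numeric(nrow(ref)))
    mat <- matrix(mat, nrow = nrow(ref))
    out[[paste0(vc, "_mean")]] <- rowMeans(mat)
    out[[paste0(vc, "_sd")]] <- if (n > 1) apply(mat, 1, stats::sd)
                                else rep(NaN, nrow(ref))
  }
  attr(out, "n_replicates") <- n
  if (n == 1L) attr(out, "flag") <- "single_replicate"
  out
}
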