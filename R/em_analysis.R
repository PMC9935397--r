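#' Radial average of a map or 2D image around the filament axis
#'
#' Mean intensity per annulus of width `dr`, computed by bilinear sampling
#' of each annulus midpoint circle (ring spacing ~`dr/2` along the arc),
#' averaged over z slices for a 3D map. The profile is truncated where
#' rings leave the grid.
#'
#' @param x A [density_map()] or a 2D numeric matrix.
#' @param center `(x, y)` center in physical units for maps (default: grid
#'   center), in pixel units for matrices (default: matrix center).
#' @param dr Radial bin width; defaults to the voxel size (1 for
#'   matrices).
#' @param r_max Maximum radius; defaults to the usable in-plane extent.
#' @return A [radial_profile()].
#' @export
radial_average <- function(x, center = NULL, dr = NULL, r_max = NULL) {
  if (inherits(x, "density_map")) {
    vs <- x$voxel_size
    # annulus means commute with the z mean, so collapse the stack first
    img_stack <- array(apply(x$data, c(1, 2), mean),
                       dim = c(dim(x$data)[1:2], 1L))
    nx <- dim(img_stack)[1]; ny <- dim(img_stack)[2]
    if (is.null(center))
      center <- c((nx + 1) / 2, (ny + 1) / 2)   # pixel units
    else
      center <- (center - x$origin[1:2]) / vs + 1
    if (is.null(dr)) dr <- vs
    scale <- vs
  } else {
    img_stack <- array(x, dim = c(dim(x), 1L))
    nx <- dim(x)[1]; ny <- dim(x)[2]
    if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
    if (is.null(dr)) dr <- 1
    scale <- 1
  }
  dr_pix <- dr / scale
  max_pix <- min(center[1] - 1, nx - center[1], center[2] - 1, ny - center[2])
  if (!is.null(r_max)) max_pix <- min(max_pix, r_max / scale)
  nbin <- floor(max_pix / dr_pix)
  if (nbin < 2L) stop("center too close to the grid edge for a radial average")
  r_pix <- (seq_len(nbin) - 0.5) * dr_pix
  nz <- dim(img_stack)[3]
  vals <- vapply(r_pix, function(rp) {
    nang <- max(16L, ceiling(2 * pi * rp / (dr_pix / 2)))
    ang <- (seq_len(nang) - 1) * 2 * pi / nang
    px <- center[1] + rp * cos(ang)
    py <- center[2] + rp * sin(ang)
    mean(vapply(seq_len(nz), function(k)
      mean(bilinear_sample(img_stack[, , k], px, py)), numeric(1)))
  }, numeric(1))
  radial_profile(r_pix * scale, vals, label = "radial_average")
}

# bilinear interpolation of matrix m at fractional pixel coords (px, py)
bilinear_sample <- function(m, px, py) {
  nx <- nrow(m); ny <- ncol(m)
  px <- pmin(pmax(px, 1), nx)
  py <- pmin(pmax(py, 1), ny)
  i0 <- pmin(floor(px), nx - 1L); j0 <- pmin(floor(py), ny - 1L)
  fx <- px - i0; fy <- py - j0
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0 + 1L, j0)] * fx * (1 - fy) +
    m[cbind(i0, j0 + 1L)] * (1 - fx) * fy +
    m[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' Normalize a map to protein intensity with zero solvent
#'
#' From the map's radial average, the solvent plateau (mean beyond
#' `solvent_r_min`, default the outermost 10% of usable radii) is
#' subtracted so solvent maps to 0, and the map is scaled so the mean
#' radial intensity within `protein_r_range` equals 1.
#'
#' @param map A [density_map()].
#' @param protein_r_range `(r_lo, r_hi)` of the protein shell, Angstrom.
#' @param solvent_r_min Radius beyond which intensity is solvent; `NULL`
#'   for the outermost-10% default.
#' @return The normalized [density_map()].
#' @export
normalize_map_to_protein <- function(map, protein_r_range,
                                     solvent_r_min = NULL) {
  prof <- radial_average(map)
  if (is.null(solvent_r_min)) solvent_r_min <- 0.9 * max(prof$r)
  solv <- mean(prof$value[prof$r >= solvent_r_min])
  prot <- mean(prof$value[prof$r >= protein_r_range[1] &
                            prof$r <= protein_r_range[2]])
  if (!is.finite(prot) || !is.finite(solv) || prot <= solv)
    stop("protein shell mean <= solvent mean: normalization undefined")
  out <- map
  out$data <- (map$data - solv) / (prot - solv)
  out
}

#' Rotationally align z slices on the helical contact sites
#'
#' Rotates the slice at height z in-plane by `-(twist / rise) * (z -
#' z_ref)` about the tubule center (bilinear interpolation), so that after
#' alignment the membrane-protein contact azimuth no longer depends on z.
#' `z_ref` defaults to the central slice.
#'
#' @param map A [density_map()] with `twist` and `rise` set.
#' @param center Physical `(x, y)` rotation center (default grid center).
#' @param z_ref Reference height, Angstrom (default central slice).
#' @return The aligned [density_map()].
#' @export
align_slices_by_contact_sites <- function(map, center = NULL, z_ref = NULL) {
  if (is.na(map$twist) || is.na(map$rise))
    stop("map lacks helical twist/rise parameters")
  d <- dim(map$data)
  if (is.null(center)) cpix <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  else cpix <- (center - map$origin[1:2]) / map$voxel_size + 1
  zg <- map_axis(map, 3L)
  if (is.null(z_ref)) z_ref <- zg[ceiling(d[3] / 2)]
  ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  dx <- ij$i - cpix[1]; dy <- ij$j - cpix[2]
  out <- map
  for (k in seq_len(d[3])) {
    # rotating the image by -(twist/rise)*(z - z_ref) means sampling the
    # source slice at positions rotated by the inverse angle
    ang <- (map$twist / map$rise) * (zg[k] - z_ref) * pi / 180
    px <- cpix[1] + dx * cos(ang) - dy * sin(ang)
    py <- cpix[2] + dx * sin(ang) + dy * cos(ang)
    out$data[, , k] <- matrix(bilinear_sample(map$data[, , k], px, py),
                              d[1], d[2])
  }
  out
}

#' Central z projection of a map
#'
#' Mean over the central `floor(fraction * Nz)` slices (at least one),
#' improving signal-to-noise before radial averaging.
#'
#' @param map A [density_map()].
#' @param fraction Fraction of slices to project (default 0.30).
#' @return 2D numeric matrix.
#' @export
central_projection <- function(map, fraction = 0.30) {
  stopifnot(fraction > 0, fraction <= 1)
  nz <- dim(map$data)[3]
  nkeep <- max(1L, floor(fraction * nz))
  lo <- floor((nz - nkeep) / 2) + 1L
  sl <- lo:(lo + nkeep - 1L)
  apply(map$data[, , sl, drop = FALSE], c(1, 2), mean)
}

#' 1D line profile through a map
#'
#' Interpolated intensity along a radial line at fixed azimuth (through
#' all z, averaged), or along the filament axis at fixed (r, theta).
#' Sample spacing equals the voxel size.
#'
#' @param map A [density_map()].
#' @param direction `"radial_at_theta"` or `"axial_at_r_theta"`.
#' @param theta Azimuth in degrees.
#' @param r Radius in Angstrom (axial mode).
#' @param z_index Slice index for the radial mode (default: central
#'   slice).
#' @param center Physical `(x, y)` center (default grid center).
#' @return data.frame `pos`, `value` (pos = r or z in Angstrom).
#' @export
line_profile <- function(map, direction = c("radial_at_theta",
                                            "axial_at_r_theta"),
                         theta = 0, r = NULL, z_index = NULL,
                         center = NULL) {
  direction <- match.arg(direction)
  d <- dim(map$data)
  vs <- map$voxel_size
  if (is.null(center)) cpix <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  else cpix <- (center - map$origin[1:2]) / vs + 1
  if (direction == "radial_at_theta") {
    if (is.null(z_index)) z_index <- ceiling(d[3] / 2)
    max_pix <- min(cpix[1] - 1, d[1] - cpix[1], cpix[2] - 1, d[2] - cpix[2])
    rp <- seq(0, max_pix, by = 1)
    px <- cpix[1] + rp * cos(theta * pi / 180)
    py <- cpix[2] + rp * sin(theta * pi / 180)
    data.frame(pos = rp * vs,
               value = bilinear_sample(map$data[, , z_index], px, py))
  } else {
    if (is.null(r)) stop("axial profile needs r")
    px <- cpix[1] + (r / vs) * cos(theta * pi / 180)
    py <- cpix[2] + (r / vs) * sin(theta * pi / 180)
    if (px < 1 || px > d[1] || py < 1 || py > d[2])
      stop("line exits the grid")
    vals <- vapply(seq_len(d[3]), function(k)
      bilinear_sample(map$data[, , k], px, py), numeric(1))
    data.frame(pos = map_axis(map, 3L), value = vals)
  }
}

#' Fit three Gaussians to a membrane radial profile
#'
#' Least-squares fit of `A1 G(mu1, s1) - A2 G(mu2, s2) + A3 G(mu3, s3)`
#' (amplitudes constrained positive) to the profile inside `window`,
#' initialized from the window's argmax / argmin / argmax. The two
#' positive components are the leaflet headgroup peaks, the negative one
#' the aliphatic trough; leaflet thicknesses are the peak-to-trough
#' distances.
#'
#' @param profile A [radial_profile()] (typically from a normalized,
#'   centrally projected map).
#' @param window `(r_lo, r_hi)` fit window containing both peaks and the
#'   trough.
#' @return List of class `gaussian_fit`: `mu`, `sigma`, `amplitude`
#'   (length-3, ordered by center), `thickness_inner`, `thickness_outer`,
#'   `asymmetry` (outer - inner), `residual_norm`, `window`, `fitted`.
#' @export
fit_three_gaussians <- function(profile, window) {
  sel <- profile$r >= window[1] & profile$r <= window[2]
  r <- profile$r[sel]; v <- profile$value[sel]
  if (length(r) < 10L) stop("fit window too narrow")
  i_max1 <- which.max(v)
  # trough: minimum between the global max and the other peak
  i_min <- which.min(v)
  left <- v[seq_len(i_min)]; right <- v[i_min:length(v)]
  i_p1 <- which.max(left)
  i_p3 <- (i_min - 1L) + which.max(right)
  if (!(i_p1 < i_min && i_min < i_p3))
    stop("window does not contain two maxima flanking a minimum")
  start <- list(A1 = max(v[i_p1], 1e-3), m1 = r[i_p1], s1 = 3,
                A2 = max(-v[i_min], 1e-3), m2 = r[i_min], s2 = 3,
                A3 = max(v[i_p3], 1e-3), m3 = r[i_p3], s3 = 3)
  fit <- minpack.lm::nlsLM(
    v ~ A1 * exp(-(r - m1)^2 / (2 * s1^2)) -
        A2 * exp(-(r - m2)^2 / (2 * s2^2)) +
        A3 * exp(-(r - m3)^2 / (2 * s3^2)),
    start = start,
    lower = c(A1 = 0, m1 = window[1], s1 = 0.3,
              A2 = 0, m2 = window[1], s2 = 0.3,
              A3 = 0, m3 = window[1], s3 = 0.3),
    upper = c(A1 = Inf, m1 = window[2], s1 = 30,
              A2 = Inf, m2 = window[2], s2 = 30,
              A3 = Inf, m3 = window[2], s3 = 30),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- stats::coef(fit)
  mu <- c(p["m1"], p["m2"], p["m3"])
  if (!(mu[1] < mu[2] && mu[2] < mu[3]))
    stop(sprintf("gaussian centers out of order: %.2f, %.2f, %.2f",
                 mu[1], mu[2], mu[3]))
  structure(list(
    mu = unname(mu),
    sigma = unname(c(p["s1"], p["s2"], p["s3"])),
    amplitude = unname(c(p["A1"], -p["A2"], p["A3"])),
    thickness_inner = unname(mu[2] - mu[1]),
    thickness_outer = unname(mu[3] - mu[2]),
    asymmetry = unname(mu[3] + mu[1] - 2 * mu[2]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    window = window,
    fitted = radial_profile(r, stats::fitted(fit), label = "3-gaussian fit")),
    class = "gaussian_fit")
}

#' Leaflet areas above solvent background
#'
#' Integrates `max(value, 0)` by the trapezoid rule on each side of the
#' leaflet split radius: the inner leaflet from the zero crossing below
#' the inner peak up to the split, the outer leaflet from the split up to
#' the zero crossing above the outer peak (so lumen and protein intensity
#' are excluded).
#'
#' @param profile A normalized [radial_profile()] (solvent = 0).
#' @param split Split radius between the leaflet peaks (typically the
#'   fitted trough center).
#' @return List `inner`, `outer` (areas), `bounds` (integration bounds),
#'   `flag` (set when a side has no positive region).
#' @export
leaflet_areas <- function(profile, split) {
  r <- profile$r; v <- profile$value
  if (split <= min(r) || split >= max(r))
    stop("split radius outside the profile range")
  below <- which(r < split)
  above <- which(r >= split)
  # peaks on each side of the split
  ip_in <- below[which.max(v[below])]
  ip_out <- above[which.max(v[above])]
  lo <- {
    neg <- which(v[seq_len(ip_in)] <= 0)
    if (length(neg)) r[max(neg)] else r[1]
  }
  hi <- {
    neg <- which(v <= 0 & seq_along(v) > ip_out)
    if (length(neg)) r[min(neg)] else r[length(r)]
  }
  area_between <- function(a, b) {
    sel <- r >= a & r <= b
    if (sum(sel) < 2L) return(0)
    trapz(r[sel], pmax(v[sel], 0))
  }
  inner <- area_between(lo, split)
  outer <- area_between(split, hi)
  flag <- character(0)
  if (inner == 0) flag <- c(flag, "inner_no_positive_region")
  if (outer == 0) flag <- c(flag, "outer_no_positive_region")
  list(inner = inner, outer = outer, bounds = c(lo, split, hi), flag = flag)
}

#' Per-leaflet composition from bromine difference areas
#'
#' For each brominated species, the leaflet areas of the unbrominated
#' reference are subtracted from the corresponding areas of that species'
#' brominated map profile; the excess (clamped at zero, clamps logged in
#' `clamped`) is divided by the species' bromine atoms per molecule, and
#' the amounts are normalized within each leaflet so compositions sum to
#' 100 mol%.
#'
#' @param profiles Named list: `reference` plus one normalized
#'   [radial_profile()] per brominated species.
#' @param br_atoms Named vector of bromine atoms per molecule.
#' @param split Leaflet split radius (fitted trough center).
#' @return data.frame `leaflet`, `species`, `excess_area`,
#'   `br_normalized_amount`, `molar_percent`, `clamped`.
#' @export
bromine_composition <- function(profiles, br_atoms, split) {
  stopifnot("reference" %in% names(profiles))
  species <- setdiff(names(profiles), "reference")
  if (!length(species)) stop("no brominated species profiles given")
  if (any(br_atoms[species] <= 0))
    stop("br_atoms must be > 0 for every brominated species")
  ref_areas <- leaflet_areas(profiles$reference, split)
  rows <- list()
  for (lf in c("inner", "outer")) {
    exc <- vapply(species, function(s)
      leaflet_areas(profiles[[s]], split)[[lf]] - ref_areas[[lf]],
      numeric(1))
    clamped <- exc < 0
    if (any(clamped))
      warning("negative bromine excess clamped to 0 for ",
              paste(species[clamped], collapse = ", "), " (", lf, ")")
    amt <- pmax(exc, 0) / br_atoms[species]
    tot <- sum(amt)
    if (tot <= 0)
      stop("all bromine-normalized amounts are zero in the ", lf,
           " leaflet: composition undefined")
    rows[[lf]] <- data.frame(leaflet = lf, species = species,
                             excess_area = unname(exc),
                             br_normalized_amount = unname(amt),
                             molar_percent = unname(100 * amt / tot),
                             clamped = unname(clamped))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end leaflet composition from a family of maps
#'
#' Runs the full bromine-difference procedure on a reference map plus one
#' brominated map per species: protein normalization, optional rotational
#' alignment on the contact sites (`mode = "contact"`) or none
#' (`mode = "bulk"`), central 30% projection, radial averaging, trough
#' fitting on the reference, leaflet integration and bromine
#' normalization. Each member may be a single map or a list of two half
#' maps; with half maps the whole analysis runs per half and the result
#' carries the mean and the between-half standard deviation.
#'
#' @param maps Named list (`reference` + species) of [density_map()]s or
#'   of 2-element lists of half maps.
#' @param br_atoms Named bromine counts per molecule.
#' @param protein_r_range Protein shell radial window for normalization.
#' @param fit_window Radial window for the three-Gaussian trough fit.
#' @param mode `"bulk"` or `"contact"`.
#' @param fraction Central projection fraction.
#' @return List: `composition` (with `_mean`/`_sd` columns when half maps
#'   are given), `thickness` (the reference-map [fit_three_gaussians()]
#'   summary, per half when available).
#' @export
em_leaflet_composition <- function(maps, br_atoms, protein_r_range,
                                   fit_window, mode = c("bulk", "contact"),
                                   fraction = 0.30) {
  mode <- match.arg(mode)
  halves <- is.list(maps$reference) && !inherits(maps$reference, "density_map")
  run_one <- function(pick) {
    profs <- lapply(maps, function(m) {
      mm <- if (halves) m[[pick]] else m
      mm <- normalize_map_to_protein(mm, protein_r_range)
      if (mode == "contact") mm <- align_slices_by_contact_sites(mm)
      img <- central_projection(mm, fraction)
      p <- radial_average(img, dr = 1)
      radial_profile(p$r * mm$voxel_size, p$value, label = "em profile")
    })
    fit <- fit_three_gaussians(profs$reference, fit_window)
    comp <- bromine_composition(profs, br_atoms, split = fit$mu[2])
    list(composition = comp, fit = fit)
  }
  if (!halves) {
    res <- run_one(1L)
    return(list(composition = res$composition, thickness = res$fit))
  }
  a <- run_one(1L); b <- run_one(2L)
  comp <- halfmap_uncertainty(a$composition, b$composition)
  list(composition = comp, thickness = list(a$fit, b$fit),
       asymmetry_mean = mean(c(a$fit$asymmetry, b$fit$asymmetry)),
       asymmetry_sd = stats::sd(c(a$fit$asymmetry, b$fit$asymmetry)))
}

#' Mean and standard deviation between two half-map analyses
#'
#' Cellwise mean and sample standard deviation of the numeric columns of
#' two congruent result tables (e.g. [bromine_composition()] outputs run
#' on each half map).
#'
#' @param result_a,result_b Congruent data.frames.
#' @return data.frame: key columns plus `<col>_mean`, `<col>_sd`.
#' @export
halfmap_uncertainty <- function(result_a, result_b) {
  if (!identical(dim(result_a), dim(result_b)) ||
      !identical(names(result_a), names(result_b)))
    stop("half-map results have mismatched shape")
  average_replicates(list(result_a, result_b))
}
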