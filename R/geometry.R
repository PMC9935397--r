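#' Assign phospholipids to inner and outer leaflets
#'
#' Single-linkage agglomerative clustering of the phospholipid phosphate
#' bead coordinates, cut at exactly two clusters. On a tubule the two
#' leaflets are two well-separated concentric point shells, so single
#' linkage separates them unambiguously. The cluster whose phosphates have
#' the larger mean distance from the tubule center is labeled `outer`.
#'
#' @param snapshot A [tubule_snapshot()].
#' @param templates Named list of [lipid_template()]s.
#' @param center Optional `(x0, y0)` tubule center used to orient the
#'   inner/outer labels; defaults to the centroid of the phosphate beads.
#' @return data.frame with columns `lipid_id`, `species`, `leaflet`
#'   (`"inner"`/`"outer"`), covering the phospholipids only (see
#'   [assign_cholesterol()] for sterols). Carries attribute
#'   `size_warning = TRUE` when the cluster size ratio exceeds 50:1.
#' @export
assign_leaflets <- function(snapshot, templates, center = NULL) {
  ref <- reference_beads(snapshot, templates, phospholipids_only = TRUE)
  if (nrow(ref) < 2L) stop("need at least 2 phospholipids to assign leaflets")
  xyz <- as.matrix(ref[, c("x", "y", "z")])
  hc <- stats::hclust(stats::dist(xyz), method = "single")
  cl <- stats::cutree(hc, k = 2L)
  sizes <- tabulate(cl, 2L)
  if (any(sizes == 0L))
    stop("degenerate clustering: fewer than 2 nonempty leaflet clusters")
  warn <- max(sizes) / min(sizes) > 50
  if (warn)
    warning("leaflet cluster size ratio > 50:1; geometry may not be a bilayer")
  if (is.null(center)) center <- c(mean(ref$x), mean(ref$y))
  rad <- sqrt((ref$x - center[1])^2 + (ref$y - center[2])^2)
  mean_r <- tapply(rad, cl, mean)
  outer_cl <- as.integer(names(mean_r)[which.max(mean_r)])
  out <- data.frame(lipid_id = ref$lipid_id, species = ref$species,
                    leaflet = ifelse(cl == outer_cl, "outer", "inner"))
  attr(out, "size_warning") <- warn
  out
}

#' Assign sterols to leaflets by nearest phosphate
#'
#' Each sterol is assigned to the leaflet of the phospholipid phosphate bead
#' nearest (Euclidean) to its hydroxyl-equivalent anchor bead. Exact
#' distance ties are broken toward the phosphate with the smaller lipid id.
#'
#' @param snapshot A [tubule_snapshot()].
#' @param labels Phospholipid leaflet labels from [assign_leaflets()].
#' @param templates Named list of [lipid_template()]s.
#' @return `labels` extended with one row per sterol.
#' @export
assign_cholesterol <- function(snapshot, labels, templates) {
  ref_all <- reference_beads(snapshot, templates)
  sterol_sp <- names(templates)[vapply(templates, is_sterol, logical(1))]
  ster <- ref_all[ref_all$species %in% sterol_sp, , drop = FALSE]
  if (!nrow(ster)) return(labels)
  phos <- ref_all[!ref_all$species %in% sterol_sp, , drop = FALSE]
  phos <- phos[order(phos$lipid_id), , drop = FALSE]
  idx <- match(phos$lipid_id, labels$lipid_id)
  if (anyNA(idx)) stop("leaflet labels missing for some phospholipids")
  pm <- as.matrix(phos[, c("x", "y", "z")])
  add <- ster[, c("lipid_id", "species")]
  add$leaflet <- vapply(seq_len(nrow(ster)), function(i) {
    d2 <- (pm[, 1] - ster$x[i])^2 + (pm[, 2] - ster$y[i])^2 +
          (pm[, 3] - ster$z[i])^2
    # which.min takes the first minimum; phosphates sorted by lipid_id,
    # so exact ties resolve to the smaller lipid_id
    labels$leaflet[idx[which.min(d2)]]
  }, character(1))
  out <- rbind(labels, add)
  out <- out[order(out$lipid_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size_warning") <- attr(labels, "size_warning")
  out
}

#' Fit the tubule center in the xy plane
#'
#' Least-squares circle fit to the protein anchor points: finds the center
#' `c = (x0, y0)` minimizing the variance of the anchor distances,
#' `sum_i (||a_i - c|| - rbar(c))^2`, by Gauss-Newton iteration started from
#' the anchor centroid.
#'
#' @param anchors data.frame with columns `x`, `y` (z ignored), or a
#'   two-column matrix.
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @return Numeric `(x0, y0)` with attributes `radius` (mean anchor radius)
#'   and `rmsd` (residual norm).
#' @export
fit_tubule_center <- function(anchors, max_iter = 100L, tol = 1e-10) {
  a <- if (is.data.frame(anchors)) as.matrix(anchors[, c("x", "y")])
       else as.matrix(anchors)[, 1:2, drop = FALSE]
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 anchors to fit a center")
  # collinearity check via smallest eigenvalue of the xy covariance
  ev <- eigen(stats::cov(a), symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-12)
    stop("anchors are collinear in xy; circle fit is degenerate")
  ctr <- colMeans(a)
  for (it in seq_len(max_iter)) {
    dx <- a[, 1] - ctr[1]
    dy <- a[, 2] - ctr[2]
    ri <- sqrt(dx^2 + dy^2)
    if (any(ri < 1e-12)) stop("anchor coincides with trial center")
    rbar <- mean(ri)
    f <- ri - rbar
    # Jacobian of residual_i wrt center: -u_i + mean(u)
    ux <- dx / ri; uy <- dy / ri
    J <- cbind(-(ux - mean(ux)), -(uy - mean(uy)))
    step <- tryCatch(solve(crossprod(J), crossprod(J, -f)),
                     error = function(e) stop("circle fit failed: ",
                                              conditionMessage(e)))
    ctr <- ctr + as.numeric(step)
    if (sqrt(sum(step^2)) < tol) break
  }
  if (it == max_iter && sqrt(sum(step^2)) >= tol)
    stop(sprintf("circle fit did not converge: residual %.3g after %d iterations",
                 sqrt(mean(f^2)), max_iter))
  dx <- a[, 1] - ctr[1]; dy <- a[, 2] - ctr[2]
  ri <- sqrt(dx^2 + dy^2)
  structure(ctr, radius = mean(ri), rmsd = sqrt(mean((ri - mean(ri))^2)))
}

#' Transform bead coordinates to cylindrical coordinates
#'
#' `r` is the distance from the tubule axis (assumed parallel to z through
#' `center`), `theta` the azimuth in degrees in `[0, 360)`, and `z` is
#' unchanged. Beads exactly on the axis get `theta = 0`.
#'
#' @param snapshot A [tubule_snapshot()], or a data.frame with `x`,`y`,`z`.
#' @param center `(x0, y0)` from [fit_tubule_center()].
#' @return data.frame with the identifying columns of the input plus `r`,
#'   `theta`, `z`; attribute `center` records the center used.
#' @export
to_cylindrical <- function(snapshot, center) {
  stopifnot(all(is.finite(center[1:2])))
  b <- if (inherits(snapshot, "tubule_snapshot")) snapshot$beads else snapshot
  dx <- b$x - center[1]
  dy <- b$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- (atan2(dy, dx) * 180 / pi) %% 360
  theta[r == 0] <- 0
  keep <- intersect(c("species", "lipid_id", "bead"), names(b))
  out <- cbind(b[, keep, drop = FALSE],
               data.frame(r = r, theta = theta, z = b$z))
  attr(out, "center") <- as.numeric(center[1:2])
  out
}

#' Angular zone specification
#'
#' Zones partition the tubule surface by azimuth relative to the protein
#' contact sites: the `contact` zone is the wedge of total width
#' `2 * wedge_halfwidth` centered on the contact-site azimuth, the `gap`
#' zone is the equal wedge centered `gap_offset` degrees away, and the
#' remainder is `other`. With `follow_helix` the contact centerline
#' co-rotates with the anchor helix as a function of z; otherwise it is a
#' fixed azimuth.
#'
#' @param wedge_halfwidth Half-width of each wedge in degrees (default 15,
#'   i.e. 30-degree wedges).
#' @param gap_offset Azimuthal offset of the gap wedge (default 180).
#' @param follow_helix Logical (default `TRUE`).
#' @return Object of class `zone_spec`.
#' @export
zone_spec <- function(wedge_halfwidth = 15, gap_offset = 180,
                      follow_helix = TRUE) {
  if (wedge_halfwidth <= 0 || wedge_halfwidth > 90)
    stop("wedge_halfwidth must be in (0, 90]")
  dsep <- circ_dist_deg(gap_offset, 0)
  if (dsep < 2 * wedge_halfwidth)
    stop("contact and gap wedges overlap")
  structure(list(wedge_halfwidth = wedge_halfwidth, gap_offset = gap_offset,
                 follow_helix = follow_helix), class = "zone_spec")
}

#' @keywords internal
circ_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Helical contact-site centerline from anchor points
#'
#' Unwraps anchor azimuth versus z and fits a line, giving the contact
#' azimuth theta_c(z) = intercept + slope * z (slope = 360/pitch in
#' degrees/Angstrom). Robust to missing subunits since the fit uses all
#' anchors jointly.
#'
#' @param anchors data.frame with `x`, `y`, `z`.
#' @param center `(x0, y0)`.
#' @return List with `intercept`, `slope`; and a function `theta_c(z)`.
#' @export
anchor_helix_fit <- function(anchors, center) {
  if (!nrow(anchors)) stop("empty anchor list")
  th <- (atan2(anchors$y - center[2], anchors$x - center[1]) * 180 / pi) %% 360
  o <- order(anchors$z)
  zs <- anchors$z[o]; ths <- th[o]
  # unwrap: accumulate jumps > 180 deg between successive anchors
  dth <- diff(ths)
  dth <- dth - 360 * round(dth / 360)
  unwrapped <- cumsum(c(ths[1], dth))
  if (length(unique(zs)) < 2L) {
    list(intercept = mean(unwrapped), slope = 0,
         theta_c = function(z) rep(mean(unwrapped) %% 360, length(z)))
  } else {
    fit <- stats::lm.fit(cbind(1, zs), unwrapped)
    b <- fit$coefficients
    list(intercept = b[1], slope = b[2],
         theta_c = function(z) (b[1] + b[2] * z) %% 360)
  }
}

#' Assign lipids to angular zones
#'
#' A lipid's zone is decided by the (theta, z) position of its phosphate
#' bead: `contact` when its circular distance to the contact centerline is
#' within the wedge half-width, `gap` when within the half-width of the
#' centerline offset by `gap_offset`, else `other`.
#'
#' @param coords Cylindrical coordinates from [to_cylindrical()].
#' @param anchors Anchor data.frame (needed when `spec$follow_helix`).
#' @param spec A [zone_spec()].
#' @param templates Named list of [lipid_template()]s (identifies each
#'   lipid's phosphate bead).
#' @return data.frame with `lipid_id`, `species`, `zone`.
#' @export
assign_zones <- function(coords, anchors, spec = zone_spec(),
                         templates = default_lipid_templates()) {
  center <- attr(coords, "center")
  if (spec$follow_helix) {
    if (is.null(anchors) || !nrow(anchors))
      stop("follow_helix requires a nonempty anchor list")
    helix <- anchor_helix_fit(anchors, center)
    theta_fun <- helix$theta_c
  } else {
    theta_fun <- function(z) rep(0, length(z))
  }
  ref <- do.call(rbind, lapply(unique(coords$species), function(sp) {
    tpl <- template_for(templates, sp)
    coords[coords$species == sp & coords$bead == tpl$phosphate_bead,
           c("lipid_id", "species", "theta", "z")]
  }))
  ref <- ref[order(ref$lipid_id), , drop = FALSE]
  tc <- theta_fun(ref$z)
  d_contact <- circ_dist_deg(ref$theta, tc)
  d_gap <- circ_dist_deg(ref$theta, tc + spec$gap_offset)
  zone <- ifelse(d_contact <= spec$wedge_halfwidth, "contact",
                 ifelse(d_gap <= spec$wedge_halfwidth, "gap", "other"))
  out <- data.frame(lipid_id = ref$lipid_id, species = ref$species,
                    zone = zone)
  rownames(out) <- NULL
  out
}

#' Zone membership for arbitrary (theta, z) points
#'
#' Bead-level zone lookup used by composition analysis (compositions gather
#' every non-headgroup bead by its own position, not its lipid's phosphate).
#'
#' @param theta,z Numeric vectors (degrees, Angstrom).
#' @param anchors,center,spec As in [assign_zones()].
#' @return Character vector of zones.
#' @export
zone_of_points <- function(theta, z, anchors, center, spec = zone_spec()) {
  if (spec$follow_helix) {
    if (is.null(anchors) || !nrow(anchors))
      stop("follow_helix requires a nonempty anchor list")
    tc <- anchor_helix_fit(anchors, center)$theta_c(z)
  } else tc <- rep(0, length(z))
  d_contact <- circ_dist_deg(theta, tc)
  d_gap <- circ_dist_deg(theta, tc + spec$gap_offset)
  ifelse(d_contact <= spec$wedge_halfwidth, "contact",
         ifelse(d_gap <= spec$wedge_halfwidth, "gap", "other"))
}
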