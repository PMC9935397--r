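#' Specification of a synthetic tubule density map
#'
#' Describes a voxelized cryo-EM-like map of a membrane nanotube as a sum
#' of cylindrical Gaussian shells around the z axis through the grid
#' center: a positive inner-leaflet headgroup shell, a negative aliphatic
#' trough shell, a positive outer-leaflet headgroup shell, and a protein
#' shell, plus optional per-species bromine contrast terms and Gaussian
#' voxel noise. Default shell radii give an inner peak-to-trough distance
#' of 6.8 A and an outer distance of 10.4 A, i.e. an inner leaflet 3.6 A
#' thinner than the outer.
#'
#' @param shape Grid dimensions (x, y, z), each >= 8.
#' @param voxel_size Voxel edge, Angstrom.
#' @param shells data.frame with columns `radius`, `width`, `amplitude`
#'   (Angstrom, Angstrom, map units): the membrane shells.
#' @param protein List `radius`, `width`, `amplitude` for the protein
#'   shell.
#' @param solvent Constant solvent background added everywhere.
#' @param leaflet_radii Named `c(inner=, outer=)` radii at which bromine
#'   contrast terms for each leaflet are deposited (defaults: the two
#'   positive shell radii).
#' @param bromine_width Gaussian width of bromine terms, Angstrom.
#' @param bromine_unit Map-unit amplitude contributed per (mol fraction x
#'   Br atom).
#' @param contact_mod `NULL`, or list `amplitude` (fractional), `kappa`
#'   (azimuthal von Mises concentration): multiplies the protein shell and
#'   outer-leaflet bromine terms by
#'   `1 + amplitude * exp(kappa * (cos(theta - theta_c(z)) - 1))` where
#'   `theta_c(z)` follows the anchor helix.
#' @param twist,rise,subunits_per_turn Helical parameters recorded on the
#'   map (and defining `theta_c(z)`).
#' @param noise_sigma Gaussian voxel noise sd, map units.
#' @param seed Integer seed for the noise.
#' @return Object of class `map_spec`.
#' @export
map_spec <- function(shape = c(96, 96, 48), voxel_size = 1.5,
                     shells = data.frame(
                       radius = c(30, 36.8, 47.2),
                       width = c(2.2, 2.8, 2.2),
                       amplitude = c(1, -0.6, 1)),
                     protein = list(radius = 58, width = 2.5,
                                    amplitude = 1.6),
                     solvent = 0,
                     leaflet_radii = NULL, bromine_width = 2.5,
                     bromine_unit = 0.15,
                     contact_mod = NULL,
                     twist = 360 / 17, rise = 3.0, subunits_per_turn = 17L,
                     noise_sigma = 0, seed = 1L) {
  if (any(shape < 8L)) stop("shape must be >= 8 along each axis")
  if (any(shells$width <= 0)) stop("shell widths must be > 0")
  half_extent <- min(shape[1:2]) / 2 * voxel_size
  if (max(shells$radius, protein$radius) > half_extent)
    stop("grid too small to contain the outermost shell")
  if (is.null(leaflet_radii)) {
    pos <- shells[shells$amplitude > 0, ]
    leaflet_radii <- c(inner = min(pos$radius), outer = max(pos$radius))
  }
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 shells = shells, protein = protein, solvent = solvent,
                 leaflet_radii = leaflet_radii,
                 bromine_width = bromine_width, bromine_unit = bromine_unit,
                 contact_mod = contact_mod, twist = twist, rise = rise,
                 subunits_per_turn = as.integer(subunits_per_turn),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "map_spec")
}

# cylindrical radius/theta/z arrays of a map grid centered on the xy middle
map_cyl_grids <- function(shape, voxel_size) {
  cx <- (shape[1] + 1) / 2
  cy <- (shape[2] + 1) / 2
  x <- (seq_len(shape[1]) - cx) * voxel_size
  y <- (seq_len(shape[2]) - cy) * voxel_size
  r2d <- sqrt(outer(x^2, y^2, "+"))
  th2d <- atan2(matrix(y, shape[1], shape[2], byrow = TRUE),
                matrix(x, shape[1], shape[2])) * 180 / pi
  z <- (seq_len(shape[3]) - 1) * voxel_size
  list(r = r2d, theta = th2d %% 360, z = z,
       origin = c(-(cx - 1) * voxel_size, -(cy - 1) * voxel_size, 0))
}

#' Generate a synthetic tubule density map
#'
#' Realizes a [map_spec()], optionally adding bromine contrast terms for a
#' ground-truth per-leaflet composition.
#'
#' @param spec A [map_spec()].
#' @param bromine `NULL` for an unbrominated reference map, or a list with
#'   `species` (name), `fractions` (named `c(inner=, outer=)` ground-truth
#'   mol fractions of that species in each leaflet) and `br_atoms` (bromine
#'   atoms per molecule): adds a Gaussian shell at each leaflet radius with
#'   amplitude `bromine_unit * fraction * br_atoms`.
#' @param seed Overrides the spec's noise seed.
#' @return A [density_map()] carrying helical parameters; attribute
#'   `ground_truth` records the spec and bromine description.
#' @export
generate_density_map <- function(spec, bromine = NULL, seed = spec$seed) {
  g <- map_cyl_grids(spec$shape, spec$voxel_size)
  nz <- spec$shape[3]
  slice0 <- matrix(spec$solvent, spec$shape[1], spec$shape[2])
  for (i in seq_len(nrow(spec$shells)))
    slice0 <- slice0 + spec$shells$amplitude[i] *
      exp(-(g$r - spec$shells$radius[i])^2 / (2 * spec$shells$width[i]^2))
  prot_slice <- spec$protein$amplitude *
    exp(-(g$r - spec$protein$radius)^2 / (2 * spec$protein$width^2))

  br_slices <- list(inner = NULL, outer = NULL)
  if (!is.null(bromine)) {
    for (lf in c("inner", "outer")) {
      amp <- spec$bromine_unit * bromine$fractions[[lf]] * bromine$br_atoms
      br_slices[[lf]] <- amp *
        exp(-(g$r - spec$leaflet_radii[[lf]])^2 /
              (2 * spec$bromine_width^2))
    }
  }

  slope <- spec$twist / spec$rise          # degrees per Angstrom
  arr <- array(0, dim = spec$shape)
  for (k in seq_len(nz)) {
    sl <- slice0
    if (!is.null(spec$contact_mod)) {
      tc <- (g$z[k] * slope) %% 360
      mod <- 1 + spec$contact_mod$amplitude *
        exp(spec$contact_mod$kappa * (cos((g$theta - tc) * pi / 180) - 1))
      sl <- sl + prot_slice * mod
      if (!is.null(br_slices$outer))
        sl <- sl + br_slices$outer * mod + br_slices$inner
    } else {
      sl <- sl + prot_slice
      if (!is.null(br_slices$outer))
        sl <- sl + br_slices$outer + br_slices$inner
    }
    arr[, , k] <- sl
  }
  if (spec$noise_sigma > 0) {
    set.seed(seed)
    arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sigma),
                       dim = spec$shape)
  }
  m <- density_map(arr, voxel_size = spec$voxel_size, origin = g$origin,
                   twist = spec$twist, rise = spec$rise,
                   subunits_per_turn = spec$subunits_per_turn)
  attr(m, "ground_truth") <- list(spec = spec, bromine = bromine)
  m
}

#' Generate a matched family of reference and brominated maps
#'
#' For a ground-truth per-leaflet composition, produces the unbrominated
#' reference map plus one map per brominated species, all sharing every
#' non-bromine term. With `half_maps = TRUE` each member is a pair of
#' independently noised maps.
#'
#' @param spec A [map_spec()].
#' @param composition Named list `inner`, `outer`: named mol-fraction
#'   vectors per species (each summing to 1).
#' @param br_atoms Named vector of bromine atoms per molecule per species.
#' @param half_maps Produce two half maps per member.
#' @param seed Base seed; member noise seeds derive from it.
#' @return Named list: `reference` and one entry per species; each entry is
#'   a [density_map()] or (with half maps) a list of two.
#' @export
generate_map_family <- function(spec, composition, br_atoms,
                                half_maps = FALSE, seed = spec$seed) {
  species <- names(composition$inner)
  stopifnot(identical(species, names(composition$outer)),
            all(species %in% names(br_atoms)))
  members <- c(list(reference = NULL),
               stats::setNames(lapply(species, function(s) list(
                 species = s,
                 fractions = c(inner = unname(composition$inner[[s]]),
                               outer = unname(composition$outer[[s]])),
                 br_atoms = unname(br_atoms[[s]]))), species))
  out <- list()
  for (i in seq_along(members)) {
    nm <- names(members)[i]
    if (half_maps) {
      out[[nm]] <- list(
        generate_density_map(spec, members[[i]], seed = seed + 1000L * i),
        generate_density_map(spec, members[[i]], seed = seed + 1000L * i + 500L))
    } else {
      out[[nm]] <- generate_density_map(spec, members[[i]],
                                        seed = seed + 1000L * i)
    }
  }
  attr(out, "ground_truth") <- list(composition = composition,
                                    br_atoms = br_atoms)
  out
}
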