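#' Default run configuration
#'
#' Configuration values driving an end-to-end run. Defaults reproduce the
#' standard analysis parameters: radial KDE bandwidth 0.5 A on a 0.2 A
#' grid to 80 A, surface maps on a 0.835 A x 1 degree grid with 15%
#' mirror padding, tilt KDE bandwidth 0.05 degrees on a 0.9 degree grid,
#' 30-degree contact/gap wedges, and central 30% z projection for maps.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = ".",
    # synthetic tubule
    tubule = list(n_lipids_total = 1300L, r_inner = 25, r_outer = 45,
                  tube_length = 102, subunits_per_turn = 17L,
                  rise_per_subunit = 3.0, anchor_radius = 55,
                  noise_sigma = 0.75),
    # analysis parameters
    radial_kde = list(bw = 0.5, dr = 0.2, r_max = 80),
    surface_grid = list(theta_spacing = 1, z_spacing = 0.835,
                        mirror_frac = 0.15),
    tilt_kde = list(bw = 0.05, grid_spacing = 0.9),
    zones = list(wedge_halfwidth = 15, gap_offset = 180,
                 follow_helix = TRUE),
    projection_fraction = 0.30,
    br_atoms = c(SDPC = 12, POPS = 2, CHOL = 2, PIP2 = 4),
    helical = list(twist = 360 / 17, rise = 3.0, subunits_per_turn = 17L),
    protein_r_range = c(53, 63),
    fit_window = c(20, 52),
    n_replicates = 3L,
    diffusion = list(n_frames = 400L, frame_dt = 1,
                     D = c(inner = 1, outer = 1))
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Values in the file override the defaults of [default_run_config()];
#' unspecified values keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

#' Validate a run configuration
#'
#' Cross-checks the configuration: helical twist times subunits per turn
#' must be ~360 degrees (warning otherwise), contact and gap wedges must
#' not overlap (error), bromine counts must be positive (error), and
#' referenced input files must exist (error).
#'
#' @param config A `run_config`.
#' @return List `errors`, `warnings` (character vectors); invisible
#'   errors are also signalled when `strict = TRUE`.
#' @param strict Stop on errors (default `FALSE`: report only).
#' @export
validate_config <- function(config, strict = FALSE) {
  errors <- character(0)
  warnings <- character(0)
  h <- config$helical
  if (!is.null(h$twist) && !is.null(h$subunits_per_turn) &&
      abs(h$twist * h$subunits_per_turn - 360) > 1)
    warnings <- c(warnings, sprintf(
      "helical twist x subunits = %.1f deg, not 360",
      h$twist * h$subunits_per_turn))
  z <- config$zones
  dsep <- circ_dist_deg(z$gap_offset, 0)
  if (z$wedge_halfwidth <= 0 || z$wedge_halfwidth > 90)
    errors <- c(errors, "wedge_halfwidth must be in (0, 90]")
  else if (dsep < 2 * z$wedge_halfwidth)
    errors <- c(errors, "contact and gap wedges overlap")
  if (any(config$br_atoms <= 0))
    errors <- c(errors, "br_atoms must be positive for brominated species")
  if (config$projection_fraction <= 0 || config$projection_fraction > 1)
    errors <- c(errors, "projection_fraction must be in (0, 1]")
  for (f in c(config$snapshot_file, config$map_files))
    if (!is.null(f) && !file.exists(f))
      errors <- c(errors, paste("input file not found:", f))
  if (strict && length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  list(errors = errors, warnings = warnings)
}

#' @keywords internal
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL    # output location does not affect results
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small stable FNV-1a hash; avoids a digest dependency
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # h * 16777619 mod 2^32 without losing precision past 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @keywords internal
xor32 <- function(a, b) {
  # xor of doubles holding 32-bit values (bitwXor needs < 2^31)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor((a - a %% 65536) / 65536, (b - b %% 65536) / 65536)
  hi * 65536 + lo
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Orchestrates simulate -> geometry -> simulation analysis on synthetic
#' ground-truth tubules (`n_replicates` independent replicates differing
#' only in seed), and the EM stage on a synthetic brominated map family.
#' All outputs (labels, composition tables, profiles, thickness and
#' composition summaries) are written under `config$out_dir` with the
#' config hash and seed recorded; a rerun with identical config and seed
#' is byte-identical.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config = default_run_config()) {
  rep_ok <- validate_config(config, strict = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  templates <- default_lipid_templates()
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  zs <- zone_spec(config$zones$wedge_halfwidth, config$zones$gap_offset,
                  config$zones$follow_helix)

  comp_reps <- list()
  for (i in seq_len(config$n_replicates)) {
    spec <- do.call(tubule_spec,
                    c(config$tubule, list(seed = config$seed + i)))
    snap <- generate_tubule_snapshot(spec, templates)
    center <- fit_tubule_center(snap$anchors)
    labels <- assign_cholesterol(snap, assign_leaflets(snap, templates,
                                                       center),
                                 templates)
    coords <- to_cylindrical(snap, center)
    comp_reps[[i]] <- zone_composition(coords, labels, snap$anchors, zs,
                                       templates)
    if (i == 1L) {
      write_results(labels, file.path(config$out_dir, "leaflet_labels.csv"),
                    metadata = meta)
      zl <- assign_zones(coords, snap$anchors, zs, templates)
      write_results(zl, file.path(config$out_dir, "zone_labels.csv"),
                    metadata = meta)
    }
  }
  comp_avg <- average_replicates(lapply(comp_reps, function(x)
    x[setdiff(names(x), "flag")]))
  write_results(comp_avg, file.path(config$out_dir, "zone_composition.csv"),
                metadata = meta, allow_na = TRUE)

  # EM stage on a matched synthetic map family (bulk mode)
  ms <- map_spec(seed = config$seed)
  fam <- generate_map_family(
    ms,
    composition = list(
      inner = c(SDPC = 0.5, CHOL = 0.2, POPS = 0.2, PIP2 = 0.1),
      outer = c(SDPC = 0.6, CHOL = 0.15, POPS = 0.15, PIP2 = 0.1)),
    br_atoms = config$br_atoms, seed = config$seed)
  em <- em_leaflet_composition(fam, config$br_atoms,
                               protein_r_range = config$protein_r_range,
                               fit_window = config$fit_window,
                               mode = "bulk",
                               fraction = config$projection_fraction)
  write_results(em$composition,
                file.path(config$out_dir, "em_composition.csv"),
                metadata = meta)
  thick <- data.frame(quantity = c("thickness_inner", "thickness_outer",
                                   "asymmetry"),
                      value = c(em$thickness$thickness_inner,
                                em$thickness$thickness_outer,
                                em$thickness$asymmetry))
  write_results(thick, file.path(config$out_dir, "em_thickness.csv"),
                metadata = meta)
  jsonlite::write_json(c(meta, list(warnings = rep_ok$warnings)),
                       file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE)
  invisible(list(composition = comp_avg, em = em))
}
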