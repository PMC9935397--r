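#' Coarse-grained lipid bead template
#'
#' A template describes the bead topology of one lipid species in a
#' coarse-grained (Martini-style) model: which bead is the phosphate
#' (reference) bead, which beads form the polar headgroup, which beads are
#' the last bead of each acyl tail, and how many beads a whole lipid
#' contributes outside its headgroup. The non-headgroup bead count is the
#' divisor used to convert bead counts to lipid equivalents when computing
#' molar compositions; headgroups are excluded because multi-bead headgroups
#' (e.g. PIP2's five beads) would otherwise dominate the count.
#'
#' @param species_name Species label, e.g. `"SDPC"`.
#' @param phosphate_bead Label of the reference bead (the phosphate for
#'   phospholipids; for sterols, the hydroxyl-equivalent anchor bead).
#' @param headgroup_beads Character vector of headgroup bead labels (may be
#'   empty, e.g. for sterols).
#' @param tail_terminal_beads Character vector of per-tail last-bead labels
#'   (sn-1 then sn-2 for phospholipids; single entry for sterols).
#' @param glycerol_beads Character vector of glycerol/linker bead labels.
#' @param all_beads Character vector of every bead label of the species, in
#'   canonical order.
#' @param head_reference_bead Label of the single bead used to represent the
#'   headgroup position in surface density maps (e.g. NC3 for SDPC, CNO for
#'   POPS, C1 for PIP2). `NA` for species without a headgroup.
#' @param br_atoms_per_molecule Nominal number of bromine atoms carried by
#'   the fully brominated form of the species (2 per double bond).
#'
#' @return An object of class `lipid_template`.
#' @seealso [default_lipid_templates()]
#' @export
lipid_template <- function(species_name, phosphate_bead, headgroup_beads,
                           tail_terminal_beads, glycerol_beads, all_beads,
                           head_reference_bead = NA_character_,
                           br_atoms_per_molecule = 0) {
  stopifnot(is.character(species_name), length(species_name) == 1L,
            is.character(phosphate_bead), length(phosphate_bead) == 1L)
  if (!phosphate_bead %in% all_beads)
    stop("phosphate/reference bead '", phosphate_bead,
         "' not among beads of ", species_name)
  if (!all(headgroup_beads %in% all_beads) ||
      !all(tail_terminal_beads %in% all_beads) ||
      !all(glycerol_beads %in% all_beads))
    stop("template for ", species_name,
         " names beads absent from its bead list")
  if (!is.na(head_reference_bead) && !head_reference_bead %in% headgroup_beads)
    stop("head_reference_bead must be one of the headgroup beads")
  if (br_atoms_per_molecule < 0)
    stop("br_atoms_per_molecule must be nonnegative")
  nonhead <- setdiff(all_beads, headgroup_beads)
  if (length(nonhead) < 1L)
    stop("template for ", species_name, " has no non-headgroup beads")
  structure(list(
    species_name = species_name,
    phosphate_bead = phosphate_bead,
    headgroup_beads = headgroup_beads,
    tail_terminal_beads = tail_terminal_beads,
    glycerol_beads = glycerol_beads,
    head_reference_bead = head_reference_bead,
    all_beads = all_beads,
    nonheadgroup_beads = nonhead,
    nonheadgroup_bead_count = length(nonhead),
    br_atoms_per_molecule = br_atoms_per_molecule
  ), class = "lipid_template")
}

#' @export
print.lipid_template <- function(x, ...) {
  cat(sprintf("<lipid_template %s: %d beads (%d non-headgroup), ref %s, Br %g>\n",
              x$species_name, length(x$all_beads), x$nonheadgroup_bead_count,
              x$phosphate_bead, x$br_atoms_per_molecule))
  invisible(x)
}

#' Default four-species nanotube lipid templates
#'
#' Templates for the coarse-grained four-lipid mixture used throughout the
#' package: SDPC (stearoyl-docosahexaenoyl-PC; 12 non-headgroup beads,
#' one-bead choline headgroup, polyunsaturated 5-bead sn-2 tail), POPS (11
#' non-headgroup beads, one-bead serine headgroup), CHOL (8 beads, hydroxyl
#' ROH anchor, no headgroup beads) and PIP2 (11 non-headgroup beads, 5-bead
#' inositol-phosphate headgroup referenced by its C1 bead).
#'
#' Nominal bromine counts correspond to full bromination of every double
#' bond (2 Br per bond): SDPC 12, POPS 2, CHOL 2, PIP2 4. Override per
#' species when measured bromination levels are available.
#'
#' @return Named list of [lipid_template()] objects.
#' @export
default_lipid_templates <- function() {
  list(
    SDPC = lipid_template(
      "SDPC", phosphate_bead = "PO4", headgroup_beads = "NC3",
      tail_terminal_beads = c("C4A", "D5B"),
      glycerol_beads = c("GL1", "GL2"),
      all_beads = c("NC3", "PO4", "GL1", "GL2",
                    "C1A", "C2A", "C3A", "C4A",
                    "D1B", "D2B", "D3B", "D4B", "D5B"),
      head_reference_bead = "NC3",
      br_atoms_per_molecule = 12),
    POPS = lipid_template(
      "POPS", phosphate_bead = "PO4", headgroup_beads = "CNO",
      tail_terminal_beads = c("C4A", "C4B"),
      glycerol_beads = c("GL1", "GL2"),
      all_beads = c("CNO", "PO4", "GL1", "GL2",
                    "C1A", "C2A", "C3A", "C4A",
                    "C1B", "C2B", "C3B", "C4B"),
      head_reference_bead = "CNO",
      br_atoms_per_molecule = 2),
    CHOL = lipid_template(
      "CHOL", phosphate_bead = "ROH", headgroup_beads = character(),
      tail_terminal_beads = "C2",
      glycerol_beads = character(),
      all_beads = c("ROH", "R1", "R2", "R3", "R4", "R5", "C1", "C2"),
      br_atoms_per_molecule = 2),
    PIP2 = lipid_template(
      "PIP2", phosphate_bead = "PO4",
      headgroup_beads = c("C1", "C2", "C3", "P4", "P5"),
      head_reference_bead = "C1",
      tail_terminal_beads = c("C4A", "C4B"),
      glycerol_beads = c("GL1", "GL2"),
      all_beads = c("C1", "C2", "C3", "P4", "P5", "PO4", "GL1", "GL2",
                    "C1A", "C2A", "C3A", "C4A",
                    "C1B", "C2B", "C3B", "C4B"),
      br_atoms_per_molecule = 4)
  )
}

is_sterol <- function(template) length(template$headgroup_beads) == 0L

#' @keywords internal
template_for <- function(templates, species) {
  tpl <- templates[[species]]
  if (is.null(tpl)) stop("no lipid template for species '", species, "'")
  tpl
}
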