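#' Single-frame tubule snapshot
#'
#' Container for one frame of a coarse-grained lipid nanotube: every lipid
#' bead (species, lipid id, bead label, Cartesian position in Angstrom) plus
#' the protein anchor points (the membrane-inserted phenylalanine pair of
#' each filament subunit) used to fit the tubule axis and define angular
#' zones. All coordinates are stored in Angstrom; unit conversion happens at
#' I/O boundaries only.
#'
#' @param beads data.frame with columns `species`, `lipid_id` (integer),
#'   `bead` (bead label), `x`, `y`, `z` (Angstrom).
#' @param anchors data.frame with columns `subunit` (integer), `x`, `y`, `z`
#'   (Angstrom); may have zero rows for protein-free tubules.
#' @param box Numeric length-3 box dimensions in Angstrom.
#' @param frame Integer frame index.
#' @param templates Optional named list of [lipid_template()]s; when given,
#'   every lipid's bead multiset is validated against its template.
#'
#' @return An object of class `tubule_snapshot`.
#' @export
tubule_snapshot <- function(beads, anchors = empty_anchors(), box,
                            frame = 0L, templates = NULL) {
  req <- c("species", "lipid_id", "bead", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("beads must have columns ", paste(req, collapse = ", "))
  if (!is.numeric(box) || length(box) != 3L || any(box <= 0))
    stop("box must be 3 positive lengths (Angstrom)")
  beads$species <- as.character(beads$species)
  beads$bead <- as.character(beads$bead)
  beads$lipid_id <- as.integer(beads$lipid_id)
  snap <- structure(list(beads = beads, anchors = anchors,
                         box = as.numeric(box), frame = as.integer(frame)),
                    class = "tubule_snapshot")
  if (!is.null(templates)) validate_snapshot(snap, templates)
  snap
}

#' @keywords internal
empty_anchors <- function() {
  data.frame(subunit = integer(), x = numeric(), y = numeric(),
             z = numeric())
}

#' Validate a snapshot's lipids against bead templates
#'
#' Checks that every species has a template and that every lipid's bead
#' label multiset equals its template's bead list.
#'
#' @param snapshot A [tubule_snapshot()].
#' @param templates Named list of [lipid_template()]s.
#' @return Invisibly `TRUE`; errors name the offending lipid.
#' @export
validate_snapshot <- function(snapshot, templates) {
  b <- snapshot$beads
  for (sp in unique(b$species)) {
    tpl <- templates[[sp]]
    if (is.null(tpl)) stop("no lipid template for species '", sp, "'")
    want <- sort(tpl$all_beads)
    rows <- b[b$species == sp, c("lipid_id", "bead")]
    got <- split(rows$bead, rows$lipid_id)
    for (id in names(got)) {
      if (!identical(sort(got[[id]]), want))
        stop("lipid_id ", id, " (", sp, ") bead set does not match its ",
             "template: has {", paste(sort(got[[id]]), collapse = ","),
             "}, expected {", paste(want, collapse = ","), "}")
    }
  }
  invisible(TRUE)
}

#' @export
print.tubule_snapshot <- function(x, ...) {
  cat(sprintf("<tubule_snapshot frame %d: %d beads, %d lipids, %d anchors, box %.1f x %.1f x %.1f A>\n",
              x$frame, nrow(x$beads), length(unique(x$beads$lipid_id)),
              nrow(x$anchors), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Extract reference (phosphate) bead coordinates per lipid
#'
#' Returns one row per lipid holding the position of its phosphate bead
#' (hydroxyl-equivalent anchor bead for sterols).
#'
#' @param snapshot A [tubule_snapshot()].
#' @param templates Named list of [lipid_template()]s.
#' @param phospholipids_only Drop sterols (species without headgroup beads).
#' @return data.frame with columns `lipid_id`, `species`, `x`, `y`, `z`.
#' @export
reference_beads <- function(snapshot, templates, phospholipids_only = FALSE) {
  b <- snapshot$beads
  keep <- rep(FALSE, nrow(b))
  for (sp in unique(b$species)) {
    tpl <- template_for(templates, sp)
    if (phospholipids_only && is_sterol(tpl)) next
    keep <- keep | (b$species == sp & b$bead == tpl$phosphate_bead)
  }
  out <- b[keep, c("lipid_id", "species", "x", "y", "z")]
  out <- out[order(out$lipid_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
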