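#' Read a coarse-grained snapshot from a GRO file
#'
#' Parses the fixed-width GROMACS coordinate format. The GRO convention is
#' mapped onto the snapshot model as: residue name = species, residue number
#' = lipid id, atom name = bead label. Coordinates and box lengths are
#' converted from nm to Angstrom. Residues whose name matches
#' `anchor_species` are collected as protein anchor points (one anchor per
#' residue, at the mean position of its beads) instead of lipids.
#'
#' @param path Path to a `.gro` file.
#' @param templates Named list of [lipid_template()]s used to validate the
#'   lipids read (set `validate = FALSE` to skip).
#' @param unknown_species `"fail"` (default) or `"ignore"`: what to do with
#'   residues that have no template and are not anchors.
#' @param anchor_species Residue names treated as protein anchors
#'   (default `"ANC"`).
#' @param validate Validate bead multisets against templates.
#' @return A [tubule_snapshot()].
#' @export
read_snapshot_gro <- function(path, templates, unknown_species = c("fail", "ignore"),
                              anchor_species = "ANC", validate = TRUE) {
  unknown_species <- match.arg(unknown_species)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("malformed GRO file (need title, count, box): ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(natoms) || natoms < 1L)
    stop("GRO parse error at line 2: bad atom count '", trimws(lines[2L]), "'")
  if (length(lines) < natoms + 3L)
    stop("GRO file truncated: expected ", natoms, " atom lines")
  atom <- lines[3:(natoms + 2L)]
  resid <- suppressWarnings(as.integer(substr(atom, 1L, 5L)))
  resname <- trimws(substr(atom, 6L, 10L))
  atomname <- trimws(substr(atom, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(atom, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(atom, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(atom, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("GRO parse error at line ", bad[1L] + 2L, ": '", atom[bad[1L]], "'")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3L]),
                                               "[[:space:]]+")[[1L]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3]))
    stop("GRO parse error: bad box line")

  is_anchor <- resname %in% anchor_species
  known <- resname %in% names(templates)
  if (unknown_species == "fail" && any(!known & !is_anchor))
    stop("unknown species in GRO file: ",
         paste(unique(resname[!known & !is_anchor]), collapse = ", "))
  keep <- known & !is_anchor

  beads <- data.frame(species = resname[keep], lipid_id = resid[keep],
                      bead = atomname[keep],
                      x = x[keep] * 10, y = y[keep] * 10, z = z[keep] * 10)
  if (any(is_anchor)) {
    ar <- data.frame(subunit = resid[is_anchor], x = x[is_anchor] * 10,
                     y = y[is_anchor] * 10, z = z[is_anchor] * 10)
    agg <- aggregate(ar[c("x", "y", "z")], by = list(subunit = ar$subunit), mean)
    anchors <- agg[order(agg$subunit), ]
    rownames(anchors) <- NULL
  } else anchors <- empty_anchors()

  tubule_snapshot(beads, anchors, box = boxv[1:3] * 10,
                  templates = if (validate) templates else NULL)
}

#' Write a snapshot to a GRO file
#'
#' Writes the standard fixed-width GRO format (positions in nm at 0.001 nm
#' precision). Anchors are written as residues named `"ANC"` with one bead
#' `"ANC"` each.
#'
#' @param snapshot A [tubule_snapshot()].
#' @param path Output path.
#' @param title Title line.
#' @return Invisibly `path`.
#' @export
write_snapshot_gro <- function(snapshot, path, title = "leafletscope snapshot") {
  b <- snapshot$beads
  a <- snapshot$anchors
  n <- nrow(b) + nrow(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, sprintf("%5d", n)), con)
  fmt <- "%5d%-5s%5s%5d%8.3f%8.3f%8.3f"
  if (nrow(b)) {
    # GRO residue/atom numbers wrap at 100000
    writeLines(sprintf(fmt, b$lipid_id %% 100000L, b$species,
                       substr(b$bead, 1L, 5L), seq_len(nrow(b)) %% 100000L,
                       b$x / 10, b$y / 10, b$z / 10), con)
  }
  if (nrow(a)) {
    writeLines(sprintf(fmt, a$subunit %% 100000L, "ANC", "ANC",
                       (nrow(b) + seq_len(nrow(a))) %% 100000L,
                       a$x / 10, a$y / 10, a$z / 10), con)
  }
  writeLines(sprintf("%10.5f%10.5f%10.5f", snapshot$box[1] / 10,
                     snapshot$box[2] / 10, snapshot$box[3] / 10), con)
  invisible(path)
}

#' Read protein anchor points from a PDB atomic model
#'
#' Thin reader for ATOM/HETATM records: selects atoms by residue name and
#' atom name pattern and returns them as anchor points in Angstrom, one
#' anchor per (chain, resSeq), at the mean position of the selected atoms.
#'
#' @param path Path to a PDB file.
#' @param resnames Residue names to select (default `"PHE"`).
#' @param atom_pattern Regular expression on atom names (default `"^C"`:
#'   side-chain/backbone carbons).
#' @return data.frame with columns `subunit`, `x`, `y`, `z`.
#' @export
read_anchors_pdb <- function(path, resnames = "PHE", atom_pattern = "^C") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM records in ", path)
  resname <- trimws(substr(lines, 18L, 20L))
  aname <- trimws(substr(lines, 13L, 16L))
  sel <- resname %in% resnames & grepl(atom_pattern, aname)
  if (!any(sel)) stop("no atoms match resnames/atom_pattern in ", path)
  lines <- lines[sel]
  chain <- substr(lines, 22L, 22L)
  resseq <- as.integer(substr(lines, 23L, 26L))
  x <- as.numeric(substr(lines, 31L, 38L))
  y <- as.numeric(substr(lines, 39L, 46L))
  z <- as.numeric(substr(lines, 47L, 54L))
  key <- paste(chain, resseq)
  agg <- aggregate(data.frame(x = x, y = y, z = z), by = list(key = key), mean)
  out <- data.frame(subunit = seq_len(nrow(agg)), x = agg$x, y = agg$y,
                    z = agg$z)
  out
}
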