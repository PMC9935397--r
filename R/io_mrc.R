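#' 3D density map container
#'
#' Holds a voxel grid (indexed `[x, y, z]`) with isotropic voxel size,
#' physical origin, and optional helical symmetry parameters (twist in
#' degrees per subunit, rise in Angstrom per subunit, subunits per turn)
#' describing the filament the map reconstructs.
#'
#' @param data 3D numeric array, at least 8 voxels along each axis.
#' @param voxel_size Voxel edge length in Angstrom.
#' @param origin Physical position of voxel `[1,1,1]` in Angstrom.
#' @param twist,rise Helical twist (degrees/subunit) and rise (Angstrom/
#'   subunit); `NA` when not applicable.
#' @param subunits_per_turn Integer subunits per helical turn; `NA` when not
#'   applicable. When both twist and subunits_per_turn are set,
#'   `twist * subunits_per_turn` must be within 2 degrees of 360.
#' @return An object of class `density_map`.
#' @export
density_map <- function(data, voxel_size, origin = c(0, 0, 0),
                        twist = NA_real_, rise = NA_real_,
                        subunits_per_turn = NA_integer_) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 8L)) stop("map dimensions must be >= 8 in each axis")
  if (!is.numeric(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0")
  if (!is.na(twist) && !is.na(subunits_per_turn) &&
      abs(abs(twist) * subunits_per_turn - 360) > 2)
    stop("twist * subunits_per_turn must be ~360 degrees")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), twist = twist, rise = rise,
                 subunits_per_turn = subunits_per_turn),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<density_map %d x %d x %d, %.3f A/voxel, twist %s deg, rise %s A>\n",
              d[1], d[2], d[3], x$voxel_size,
              format(x$twist), format(x$rise)))
  invisible(x)
}

#' Physical axis coordinate grids of a map
#' @keywords internal
map_axis <- function(map, axis) {
  n <- dim(map$data)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$voxel_size
}

#' Read an MRC/CCP4 (MRC2014) density map
#'
#' Reads modes 0 (int8), 1 (int16) and 2 (float32); other modes raise an
#' error naming the mode. The axis order given by the MAPC/MAPR/MAPS header
#' fields is normalized so the returned array is indexed `[x, y, z]`. Voxel
#' size is taken from the cell dimensions divided by the grid sampling and
#' must be isotropic within 1%. The origin is taken from the ORIGIN header
#' fields, falling back to NXSTART-style start indices when ORIGIN is all
#' zero.
#'
#' @param path Path to an `.mrc`/`.map` file.
#' @return A [density_map()] (helical parameters unset).
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("truncated MRC header in ", path)
  machst <- hdr_raw[213:214]
  endian <- if (identical(as.integer(machst), c(0x11L, 0x11L))) "big" else "little"
  geti <- function(word, n = 1L)
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word + n - 1L) * 4L)],
            "integer", n = n, size = 4L, endian = endian)
  getf <- function(word, n = 1L)
    readBin(hdr_raw[((word - 1L) * 4L + 1L):((word + n - 1L) * 4L)],
            "numeric", n = n, size = 4L, endian = endian)
  map_magic <- rawToChar(hdr_raw[209:212])
  if (!grepl("^MAP", map_magic))
    warning("missing MAP magic in MRC header; attempting to read anyway")
  nc <- geti(1L); nr <- geti(2L); ns <- geti(3L)
  mode <- geti(4L)
  nstart <- geti(5L, 3L)
  m <- geti(8L, 3L)
  cella <- getf(11L, 3L)
  mapcrs <- geti(17L, 3L)
  nsymbt <- geti(24L)
  origin_hdr <- getf(50L, 3L)
  if (any(c(nc, nr, ns) < 1L) || any(c(nc, nr, ns) > 1e5))
    stop("implausible MRC dimensions in ", path)
  nvox <- as.double(nc) * nr * ns
  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = TRUE, endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = endian),
    stop("unsupported MRC mode ", mode, " in ", path))
  if (length(vals) < nvox) stop("truncated MRC data block in ", path)
  a <- array(vals, dim = c(nc, nr, ns))
  # normalize column/row/section axes to x,y,z
  if (any(sort(mapcrs) != 1:3)) stop("invalid MAPC/MAPR/MAPS in ", path)
  perm <- match(1:3, mapcrs)
  a <- aperm(a, perm)
  m_xyz <- m
  vox <- cella / pmax(m_xyz, 1L)
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("invalid cell/grid sampling in ", path)
  if ((max(vox) - min(vox)) / mean(vox) > 0.01)
    stop(sprintf("nonuniform voxel size beyond 1%%: %.4f/%.4f/%.4f A",
                 vox[1], vox[2], vox[3]))
  vs <- mean(vox)
  origin <- if (any(origin_hdr != 0)) origin_hdr
            else nstart[perm] * vs
  density_map(a, voxel_size = vs, origin = origin)
}

#' Write a density map in MRC2014 format
#'
#' Writes mode 2 (float32), axis order x,y,z, little-endian, with cell
#' dimensions `dim * voxel_size` and the map origin in the ORIGIN fields.
#'
#' @param map A [density_map()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_density_map <- function(map, path) {
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.numeric(map$data)
  wi(d)                              # NX NY NZ
  wi(2L)                             # MODE float32
  wi(c(0L, 0L, 0L))                  # NXSTART
  wi(d)                              # MX MY MZ
  wf(d * map$voxel_size)             # CELLA
  wf(c(90, 90, 90))                  # CELLB
  wi(1:3)                            # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))     # DMIN DMAX DMEAN
  wi(c(1L, 0L))                      # ISPG, NSYMBT
  wi(c(0L, 0L))                      # extra words 25-26
  writeBin(charToRaw("MRC "), con)   # EXTTYP (word 27)
  wi(20140L)                         # NVERSION (word 28)
  wi(rep(0L, 21L))                   # extra words 29-49
  wf(map$origin)                     # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)   # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST
  wf(stats::sd(v))                   # RMS
  wi(0L)                             # NLABL
  writeBin(raw(800L), con)           # labels
  wf(v)
  invisible(path)
}
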