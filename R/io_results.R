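#' Write an analysis result table or profile to disk
#'
#' Writes a data.frame (composition table, radial profile, ...) as CSV or
#' JSON with a small metadata block (config hash, seed, package version)
#' recorded as `#`-prefixed header lines (CSV) or a `metadata` element
#' (JSON). Column order is preserved deterministically and floats are
#' written at fixed precision so identical inputs give byte-identical files.
#'
#' @param x data.frame of results.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param metadata Named list recorded alongside the results (e.g. seed,
#'   config hash); package version is always added.
#' @param digits Decimal digits for numeric columns (default 6).
#' @param allow_na Permit `NA`/`NaN` values (default `FALSE`: a
#'   non-finite value without the flag is a validation error).
#' @return Invisibly `path`.
#' @export
write_results <- function(x, path, format = c("csv", "json"),
                          metadata = list(), digits = 6L, allow_na = FALSE) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  num <- vapply(x, is.numeric, logical(1))
  if (!allow_na) {
    bad <- vapply(x[num], function(col) any(!is.finite(col)), logical(1))
    if (any(bad))
      stop("non-finite values in column(s) ",
           paste(names(bad)[bad], collapse = ", "),
           " (use allow_na = TRUE to permit flagged missing values)")
  }
  meta <- c(list(package = paste0("leafletscope ",
                                  as.character(utils::packageVersion("leafletscope")))),
            metadata)
  out <- x
  out[num] <- lapply(out[num], function(col) {
    ifelse(is.finite(col), formatC(col, digits = digits, format = "f"), "NA")
  })
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
      writeLines(sprintf("# %s: %s", k, as.character(meta[[k]])), con)
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(metadata = meta, results = out), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Write a radial profile as CSV
#'
#' Convenience wrapper: columns `r`, `value` and, when present, `sd`.
#'
#' @param profile A [radial_profile()].
#' @param path Output path.
#' @param metadata Passed to [write_results()].
#' @return Invisibly `path`.
#' @export
write_profile <- function(profile, path, metadata = list()) {
  df <- as.data.frame(profile)
  write_results(df, path, format = "csv",
                metadata = c(list(label = attr(profile, "label")), metadata),
                allow_na = TRUE)
}

#' Radial profile object
#'
#' A 1D intensity or bead-density profile versus radius, on a uniform grid.
#'
#' @param r Strictly increasing, uniformly spaced radii (Angstrom).
#' @param value Profile values (same length as `r`).
#' @param sd Optional pointwise uncertainty.
#' @param label Provenance string.
#' @return data.frame of class `radial_profile` with attribute `label`.
#' @export
radial_profile <- function(r, value, sd = NULL, label = "") {
  stopifnot(length(r) == length(value), length(r) >= 2L)
  dr <- diff(r)
  if (any(dr <= 0)) stop("r grid must be strictly increasing")
  if ((max(dr) - min(dr)) > 1e-6 * mean(dr))
    stop("r grid must be uniformly spaced")
  df <- data.frame(r = r, value = value)
  if (!is.null(sd)) df$sd <- sd
  structure(df, class = c("radial_profile", "data.frame"), label = label)
}
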