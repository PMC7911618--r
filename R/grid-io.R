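#' Read an ESRI ASCII grid
#'
#' Parses the 6-line ESRI ASCII header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by row-major values
#' ordered north to south.
#'
#' @param path Path to a `.asc` file.
#' @param name Layer name; defaults to the file name without extension.
#' @param units Optional units label.
#' @return A [raster_layer()].
#' @export
read_esri_ascii <- function(path, name = NULL, units = "") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, n = 6L, warn = FALSE)
  if (length(lines) < 6L) {
    abort(sprintf("Malformed ESRI ASCII header in %s: expected 6 header lines.",
                  path))
  }
  hdr <- list()
  for (i in seq_len(6L)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2])))) {
      abort(sprintf("Malformed ESRI ASCII header at line %d: \"%s\"",
                    i, lines[[i]]))
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
              "nodata_value")
  missing <- setdiff(needed, names(hdr))
  if (length(missing)) {
    abort(sprintf("ESRI ASCII header in %s is missing: %s.",
                  path, paste(missing, collapse = ", ")))
  }
  spec <- grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                    hdr$cellsize, nodata = hdr$nodata_value)
  vals <- scan(path, what = numeric(), skip = 6L, quiet = TRUE)
  expected <- spec$n_rows * spec$n_cols
  if (length(vals) != expected) {
    abort(sprintf(
      "ESRI ASCII body of %s has %d values but the header implies %d (%d rows x %d cols).",
      path, length(vals), expected, spec$n_rows, spec$n_cols))
  }
  m <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(name, spec, m, units = units)
}

#' Write an ESRI ASCII grid
#'
#' Writes a layer so that [read_esri_ascii()] reproduces all finite
#' values and the grid geometry exactly; nodata cells are written as the
#' sentinel and the header is printed at full double precision.
#'
#' @param layer A [raster_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  spec <- layer$spec
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- c(
    paste("ncols", spec$n_cols),
    paste("nrows", spec$n_rows),
    paste("xllcorner", num(spec$x_ll)),
    paste("yllcorner", num(spec$y_ll)),
    paste("cellsize", num(spec$cell_size)),
    paste("NODATA_value", num(spec$nodata))
  )
  m <- layer$values
  m[!is.finite(m)] <- spec$nodata
  body <- apply(m, 1, function(r) paste(num(r), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(sprintf("Cannot write ESRI ASCII grid to %s", path))
  invisible(path)
}

#' Read an occurrence table
#'
#' Reads a delimited samples-with-data table with a header row and at
#' least the columns `species`, `longitude` and `latitude` (any order,
#' extra columns ignored).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `species`, `longitude`, `latitude`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  needed <- c("species", "longitude", "latitude")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("Occurrence file %s is missing columns: %s.",
                  path, paste(missing, collapse = ", ")))
  }
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad)) {
    abort(sprintf("Non-numeric coordinates in %s at row(s): %s.",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  tibble(species = as.character(df$species), longitude = lon, latitude = lat)
}

#' Write an occurrence table
#'
#' @param occurrences A data frame with `species`, `longitude`,
#'   `latitude` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  occurrences <- as_occurrences(occurrences)
  write.csv(occurrences, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_occurrences <- function(occurrences) {
  if (!is.data.frame(occurrences)) {
    abort("`occurrences` must be a data frame with species/longitude/latitude.")
  }
  names(occurrences) <- tolower(names(occurrences))
  needed <- c("species", "longitude", "latitude")
  missing <- setdiff(needed, names(occurrences))
  if (length(missing)) {
    abort(sprintf("`occurrences` is missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(occurrences$longitude)) ||
      !all(is.finite(occurrences$latitude))) {
    abort("Occurrence coordinates must be finite.")
  }
  as_tibble(occurrences[needed])
}

#' Extract stack values at point locations
#'
#' Maps each point to the cell containing it (half-open cells,
#' cell-centre registration; points on a shared boundary belong to the
#' cell to the east/south except at the extent edge) and returns the
#' value of every layer there. A point is flagged invalid when it falls
#' outside the extent or on a cell where any layer is nodata.
#'
#' @param stack A [raster_stack()].
#' @param points A data frame with `longitude` and `latitude` columns.
#' @return A tibble with one row per point: `longitude`, `latitude`,
#'   `row`, `col`, `valid`, and one column per layer.
#' @export
extract_values <- function(stack, points) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!length(stack$layers)) abort("`stack` has no layers.")
  points <- as.data.frame(points)
  names(points) <- tolower(names(points))
  if (!all(c("longitude", "latitude") %in% names(points))) {
    abort("`points` must have longitude and latitude columns.")
  }
  rc <- point_to_cell(stack$spec, points$longitude, points$latitude)
  inside <- !is.na(rc$row)
  vals <- matrix(NA_real_, nrow(points), length(stack$layers),
                 dimnames = list(NULL, names(stack)))
  if (any(inside)) {
    ij <- cbind(rc$row[inside], rc$col[inside])
    for (nm in names(stack)) {
      vals[inside, nm] <- stack$layers[[nm]]$values[ij]
    }
  }
  valid <- inside & apply(is.finite(vals), 1, all)
  out <- tibble(longitude = points$longitude, latitude = points$latitude,
                row = rc$row, col = rc$col, valid = valid)
  dplyr::bind_cols(out, as_tibble(vals))
}
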