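#' Grid geometry for aligned raster layers
#'
#' A `grid_spec` records the geometry shared by every layer of a stack:
#' grid dimensions, the lower-left corner of the extent (degrees), the
#' square cell size (degrees) and the nodata sentinel. Rows are stored
#' north to south: row 1 of a value matrix is the northernmost row.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_ll,y_ll Longitude/latitude of the lower-left corner of the
#'   extent, in degrees.
#' @param cell_size Cell side length in degrees (cells are square).
#' @param nodata Sentinel value marking missing cells.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(60, 80, x_ll = 100, y_ll = 20, cell_size = 0.05)
grid_spec <- function(n_rows, n_cols, x_ll, y_ll, cell_size,
                      nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a positive number of degrees.")
  }
  if (!is.finite(x_ll) || !is.finite(y_ll)) {
    abort("`x_ll` and `y_ll` must be finite coordinates.")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         x_ll = as.numeric(x_ll), y_ll = as.numeric(y_ll),
         cell_size = as.numeric(cell_size), nodata = as.numeric(nodata)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d rows x %d cols, cell %g deg, ll corner (%g, %g), nodata %g\n",
    x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll, x$nodata))
  invisible(x)
}

#' @export
format.grid_spec <- function(x, ...) {
  sprintf("%dx%d @ %g deg", x$n_rows, x$n_cols, x$cell_size)
}

spec_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "x_ll", "y_ll",
                                "cell_size", "nodata")],
                   unclass(b)[c("n_rows", "n_cols", "x_ll", "y_ll",
                                "cell_size", "nodata")],
                   tolerance = 0))
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A tibble with `row`, `col` (matrix indices, row 1 = north),
#'   `longitude` and `latitude` of every cell centre.
#' @export
cell_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  row <- rep(seq_len(spec$n_rows), times = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), each = spec$n_rows)
  tibble(
    row = row, col = col,
    longitude = spec$x_ll + (col - 0.5) * spec$cell_size,
    latitude = spec$y_ll + (spec$n_rows - row + 0.5) * spec$cell_size
  )
}

# Map points to containing cells under half-open, cell-centre-registered
# cells. Points on an interior vertical boundary belong to the cell to the
# east; points on an interior horizontal boundary to the cell to the south;
# points on the extent edge are pulled inside. Returns matrix row/col
# (row 1 = north) with NA for points outside the extent.
point_to_cell <- function(spec, longitude, latitude) {
  stopifnot(length(longitude) == length(latitude))
  xmax <- spec$x_ll + spec$n_cols * spec$cell_size
  ymax <- spec$y_ll + spec$n_rows * spec$cell_size

  col <- floor((longitude - spec$x_ll) / spec$cell_size)
  # east extent edge belongs to the last column
  col[longitude == xmax] <- spec$n_cols - 1
  # horizontal boundaries go to the southern cell: ceiling - 1
  row_s <- ceiling((latitude - spec$y_ll) / spec$cell_size) - 1
  row_s[latitude == spec$y_ll] <- 0

  outside <- !is.finite(longitude) | !is.finite(latitude) |
    longitude < spec$x_ll | longitude > xmax |
    latitude < spec$y_ll | latitude > ymax
  col[outside] <- NA_real_
  row_s[outside] <- NA_real_
  tibble(row = spec$n_rows - row_s, col = col + 1)
}

#' Environmental raster layer
#'
#' A named grid of values over a [grid_spec()]. Values are stored as an
#' `n_rows x n_cols` matrix whose first row is the northernmost row; cells
#' equal to the spec's nodata sentinel are stored as `NA` and excluded
#' from all downstream computation.
#'
#' @param name Variable name (e.g. `"bio1"`, `"ndvi"`).
#' @param spec A [grid_spec()].
#' @param values Numeric matrix matching the spec's dimensions. `NA` and
#'   cells equal to `spec$nodata` are treated as missing.
#' @param units Free-text units label.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(name, spec, values, units = "") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols))) {
    abort(sprintf("`values` must be a %d x %d matrix to match the spec.",
                  spec$n_rows, spec$n_cols))
  }
  mode(values) <- "numeric"
  values[values == spec$nodata] <- NA_real_
  structure(
    list(name = as.character(name), spec = spec, values = values,
         units = as.character(units)),
    class = "raster_layer"
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_layer> %s (%s), %s; %d valid cells",
              x$name, if (nzchar(x$units)) x$units else "unitless",
              format(x$spec), length(v)))
  if (length(v)) cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @describeIn raster_layer Convert a layer to a tibble of cell centres
#'   and values (valid cells only unless `na.rm = FALSE`).
#' @param x A `raster_layer`.
#' @param na.rm Drop nodata cells? Default `TRUE`.
#' @param ... Unused.
#' @export
as_tibble.raster_layer <- function(x, ..., na.rm = TRUE) {
  out <- cell_centers(x$spec)
  out$value <- x$values[cbind(out$row, out$col)]
  if (na.rm) out <- out[is.finite(out$value), ]
  out
}

#' Stack of aligned raster layers
#'
#' @param layers A list of [raster_layer()] objects sharing an identical
#'   [grid_spec()] and carrying unique names.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  if (inherits(layers, "raster_layer")) layers <- list(layers)
  if (!length(layers)) abort("A raster stack needs at least one layer.")
  ok <- vapply(layers, inherits, logical(1), "raster_layer")
  if (!all(ok)) abort("All elements of `layers` must be raster_layer objects.")
  nm <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nm)) abort("Layer names must be unique.")
  spec <- layers[[1]]$spec
  aligned <- vapply(layers, function(l) spec_equal(l$spec, spec), logical(1))
  if (!all(aligned)) {
    abort(sprintf("Layers are not aligned: %s differ in grid geometry.",
                  paste(nm[!aligned], collapse = ", ")))
  }
  names(layers) <- nm
  structure(list(spec = spec, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers on %s: %s\n",
              length(x$layers), format(x$spec),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' @export
`[[.raster_stack` <- function(x, i) x$layers[[i]]

#' @export
length.raster_stack <- function(x) length(x$layers)

# Logical matrix: TRUE where every layer is valid (nodata propagates).
stack_valid_mask <- function(stack) {
  m <- matrix(TRUE, stack$spec$n_rows, stack$spec$n_cols)
  for (l in stack$layers) m <- m & is.finite(l$values)
  m
}

# n_valid x n_layers matrix of values at jointly valid cells, with the
# row/col of each cell attached.
stack_valid_values <- function(stack) {
  mask <- stack_valid_mask(stack)
  idx <- which(mask)
  vals <- vapply(stack$layers, function(l) l$values[idx],
                 numeric(length(idx)))
  if (length(idx) == 1L) vals <- matrix(vals, nrow = 1,
                                        dimnames = list(NULL, names(stack)))
  rc <- arrayInd(idx, dim(mask))
  list(values = vals, row = rc[, 1], col = rc[, 2], index = idx)
}
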