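#' Classify a suitability map into habitat classes
#'
#' Bins suitability into four classes: 0 unsuitable (`p < t1`), 1 poorly
#' suitable (`t1 <= p < t2`), 2 moderately suitable (`t2 <= p < t3`),
#' 3 highly suitable (`p >= t3`), with default thresholds
#' `(0.1, 0.3, 0.6)`. Bins are lower-closed (a boundary value belongs to
#' the upper class).
#'
#' @param suitability A suitability [raster_layer()] with values in
#'   `[0, 1]`.
#' @param thresholds Ascending vector `(t1, t2, t3)`.
#' @return A [raster_layer()] of class codes, of class `classified_map`
#'   with the thresholds in attribute `"thresholds"`.
#' @export
classify <- function(suitability, thresholds = c(0.1, 0.3, 0.6)) {
  stopifnot(inherits(suitability, "raster_layer"))
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be three ascending values.")
  }
  v <- suitability$values
  fin <- v[is.finite(v)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1)) {
    abort("Suitability values must lie in [0, 1].")
  }
  cls <- (v >= thresholds[1]) + (v >= thresholds[2]) + (v >= thresholds[3])
  out <- raster_layer("suitability_class", suitability$spec, cls,
                      units = "class")
  class(out) <- c("classified_map", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Spherical area of a grid cell row
#'
#' Area of one cell in row `row` (row 1 = north) on a sphere of radius
#' 6371 km: `R^2 * dlambda * (sin(phi_top) - sin(phi_bot))`.
#'
#' @param spec A [grid_spec()].
#' @param row Matrix row index (vectorized).
#' @return Cell area(s) in km^2.
#' @export
cell_area_km2 <- function(spec, row) {
  stopifnot(inherits(spec, "grid_spec"))
  phi_top <- (spec$y_ll + (spec$n_rows - row + 1) * spec$cell_size) * pi / 180
  phi_bot <- (spec$y_ll + (spec$n_rows - row) * spec$cell_size) * pi / 180
  EARTH_RADIUS_KM^2 * (spec$cell_size * pi / 180) *
    (sin(phi_top) - sin(phi_bot))
}

# total spherical area (km^2) of the cells where mask is TRUE
mask_area_km2 <- function(spec, mask) {
  rows <- row(mask)[mask]
  sum(cell_area_km2(spec, rows))
}

#' Suitable-area summary of a classified map
#'
#' Sums spherical cell areas per habitat class, reported in 10^4 km^2.
#'
#' @param classified A [classify()] result.
#' @param period Label for the period/scenario column.
#' @param digits Rounding of the reported areas (default 2 decimals);
#'   `NULL` disables rounding.
#' @return A one-row tibble: `period`, `highly`, `moderately`, `poorly`,
#'   `total` (total = classes 1-3).
#' @export
area_summary <- function(classified, period = "current", digits = 2) {
  stopifnot(inherits(classified, "classified_map"))
  v <- classified$values
  area_of <- function(code) {
    m <- !is.na(v) & v == code
    mask_area_km2(classified$spec, m) / 1e4
  }
  a <- c(highly = area_of(3), moderately = area_of(2), poorly = area_of(1))
  out <- tibble(period = period, highly = a[["highly"]],
                moderately = a[["moderately"]], poorly = a[["poorly"]],
                total = sum(a))
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits)))
  }
  out
}

#' Percent change between two area summaries
#'
#' `100 * (future - current) / current` per class and for the total,
#' rounded to two decimals, plus the absolute change and the fold change
#' (`(future - current) / current`, the "x times" phrasing used when it
#' reaches 1).
#'
#' @param current,future One-row area summaries from [area_summary()]
#'   (or any one-row data frames with `highly`, `moderately`, `poorly`,
#'   `total` columns).
#' @param digits Rounding of percentages (default 2).
#' @return A tibble with one row per class (`highly`, `moderately`,
#'   `poorly`, `total`): current and future areas, `change_abs`,
#'   `change_pct`, `fold_change`. Classes with zero current area get
#'   `NA` percent (absolute change only).
#' @export
percent_change <- function(current, future, digits = 2) {
  classes <- c("highly", "moderately", "poorly", "total")
  missing <- setdiff(classes, intersect(names(current), names(future)))
  if (length(missing)) {
    abort(sprintf("Area summaries are missing columns: %s.",
                  paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(classes, function(cl) {
    cur <- as.numeric(current[[cl]][1])
    fut <- as.numeric(future[[cl]][1])
    d <- fut - cur
    tibble(class = cl, current = cur, future = fut,
           change_abs = round(d, digits),
           change_pct = if (cur > 0) round(100 * d / cur, digits)
                        else NA_real_,
           fold_change = if (cur > 0) round(d / cur, digits) else NA_real_)
  })
}

#' Binarize a classified map
#'
#' @param classified A [classify()] result.
#' @param min_class Lowest class treated as suitable (default 1, any
#'   suitable; 3 keeps only the highly suitable class).
#' @return A [raster_layer()] of 0/1 values (nodata preserved).
#' @export
binarize <- function(classified, min_class = 1) {
  stopifnot(inherits(classified, "classified_map"))
  v <- classified$values
  out <- raster_layer("binary_suitable", classified$spec,
                      (v >= min_class) * 1, units = "binary")
  class(out) <- c("binary_map", class(out))
  out
}

#' Range change between two binary suitability maps
#'
#' Cell-wise comparison of a current and a future binary map:
#' gain = future and not current, loss = current and not future,
#' unchanged = both. Satisfies `unchanged + loss = current area` and
#' `unchanged + gain = future area` exactly at cell level.
#'
#' @param current,future Binary [raster_layer()]s on the same grid.
#' @param period Label for the reported row.
#' @param digits Rounding of reported areas in 10^4 km^2 (default 2).
#' @return A list of class `range_change` with the three cell masks
#'   (`raster_layer`s) and a one-row `summary` tibble (`period`, `loss`,
#'   `gain`, `unchanged` in 10^4 km^2, unrounded copies in attribute
#'   `"exact"`).
#' @export
range_change <- function(current, future, period = "future", digits = 2) {
  stopifnot(inherits(current, "raster_layer"),
            inherits(future, "raster_layer"))
  if (!spec_equal(current$spec, future$spec)) {
    abort("Current and future maps are on different grids.")
  }
  cur <- current$values > 0 & !is.na(current$values)
  fut <- future$values > 0 & !is.na(future$values)
  spec <- current$spec
  masks <- list(
    gain = raster_layer("gain", spec, (fut & !cur) * 1),
    loss = raster_layer("loss", spec, (cur & !fut) * 1),
    unchanged = raster_layer("unchanged", spec, (cur & fut) * 1)
  )
  exact <- vapply(masks, function(m) {
    mask_area_km2(spec, m$values > 0 & !is.na(m$values)) / 1e4
  }, numeric(1))
  summary <- tibble(period = period,
                    loss = round(exact[["loss"]], digits),
                    gain = round(exact[["gain"]], digits),
                    unchanged = round(exact[["unchanged"]], digits))
  attr(summary, "exact") <- exact
  structure(c(masks, list(summary = summary)), class = "range_change")
}

#' @export
print.range_change <- function(x, ...) {
  cat("<range_change>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.range_change <- function(x, ...) x$summary

#' Centroid of a suitable range
#'
#' Area-weighted mean of the cell-centre coordinates of the suitable
#' cells (cells with value >= 1), weighting each cell by its spherical
#' area.
#'
#' @param mask A binary (or classified) [raster_layer()].
#' @return A one-row tibble `longitude`, `latitude`.
#' @export
centroid <- function(mask) {
  stopifnot(inherits(mask, "raster_layer"))
  v <- mask$values
  sel <- !is.na(v) & v >= 1
  if (!any(sel)) abort("Mask is empty: centroid undefined.")
  spec <- mask$spec
  rows <- row(v)[sel]
  cols <- col(v)[sel]
  wt <- cell_area_km2(spec, rows)
  tibble(
    longitude = sum((spec$x_ll + (cols - 0.5) * spec$cell_size) * wt) / sum(wt),
    latitude = sum((spec$y_ll + (spec$n_rows - rows + 0.5) * spec$cell_size) *
                     wt) / sum(wt)
  )
}

#' Centroid displacement between two periods
#'
#' @param from,to One-row `longitude`/`latitude` tibbles (from
#'   [centroid()]).
#' @return A one-row tibble: from/to coordinates, `delta_latitude`
#'   (degrees) and haversine `distance_km` on a 6371 km sphere.
#' @export
centroid_shift <- function(from, to) {
  d <- geosphere::distHaversine(
    c(from$longitude[1], from$latitude[1]),
    c(to$longitude[1], to$latitude[1]),
    r = EARTH_RADIUS_KM * 1000) / 1000
  tibble(from_longitude = from$longitude[1], from_latitude = from$latitude[1],
         to_longitude = to$longitude[1], to_latitude = to$latitude[1],
         delta_latitude = to$latitude[1] - from$latitude[1],
         distance_km = d)
}
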