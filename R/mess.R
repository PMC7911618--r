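#' Multivariate environmental similarity surface (MESS)
#'
#' For each cell and variable, with `f` the percentage of reference
#' values strictly below the cell value, the similarity is
#' \itemize{
#'   \item `100 * (v - min) / (max - min)` when `f = 0` (negative below
#'     the reference minimum),
#'   \item `2 f` when `0 < f <= 50`,
#'   \item `2 (100 - f)` when `50 < f < 100`,
#'   \item `100 * (max - v) / (max - min)` when `f = 100` (negative
#'     above the reference maximum).
#' }
#' The cell's `S` is the minimum over variables; `S = 100` is attained
#' only at the multivariate reference median, and `S < 0` exactly when
#' at least one variable is outside its reference range (extrapolation).
#'
#' @param reference Data frame of reference samples, one column per
#'   variable (at least 2 values each, non-constant).
#' @param stack Projection [raster_stack()] carrying (at least) the
#'   reference variables.
#' @return A list of class `mess_map`: `similarity` (a
#'   [raster_layer()] of `S`), `most_dissimilar` (a `raster_layer` of
#'   variable indices) and `variables` (the index-to-name key).
#' @export
mess <- function(reference, stack) {
  stopifnot(inherits(stack, "raster_stack"))
  reference <- as.data.frame(reference)
  vars <- intersect(names(stack), colnames(reference))
  if (!length(vars)) abort("No shared variables between reference and stack.")
  for (v in vars) {
    rv <- reference[[v]]
    rv <- rv[is.finite(rv)]
    if (length(rv) < 2) abort(sprintf("Reference for `%s` needs >= 2 values.", v))
    if (min(rv) == max(rv)) {
      abort(sprintf("Reference for `%s` is constant (min = max).", v))
    }
  }
  spec <- stack$spec
  s_all <- array(NA_real_, c(spec$n_rows, spec$n_cols, length(vars)))
  for (k in seq_along(vars)) {
    v <- vars[k]
    rv <- sort(reference[[v]][is.finite(reference[[v]])])
    n <- length(rv)
    rmin <- rv[1]; rmax <- rv[n]
    cellv <- stack$layers[[v]]$values
    # percent of reference values strictly below the cell value;
    # strict "<" resolves ties toward smaller f
    f <- 100 * (findInterval(cellv, rv, left.open = TRUE)) / n
    s <- ifelse(f == 0, 100 * (cellv - rmin) / (rmax - rmin),
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (rmax - cellv) / (rmax - rmin))))
    s[!is.finite(cellv)] <- NA_real_
    s_all[, , k] <- s
  }
  s_min <- apply(s_all, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)
  })
  which_min <- apply(s_all, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else which.min(z)
  })
  structure(
    list(similarity = raster_layer("mess_similarity", spec, s_min,
                                   units = "S"),
         most_dissimilar = raster_layer("most_dissimilar", spec, which_min,
                                        units = "variable index"),
         variables = vars),
    class = "mess_map"
  )
}

#' @export
print.mess_map <- function(x, ...) {
  v <- x$similarity$values
  v <- v[is.finite(v)]
  cat(sprintf(
    "<mess_map> %d variables; S range [%.2f, %.2f]; %.1f%% extrapolation cells\n",
    length(x$variables), min(v), max(v), 100 * mean(v < 0)))
  invisible(x)
}

#' Mean MESS similarity at a point set
#'
#' @param messmap A [mess()] result.
#' @param points Data frame with `longitude`/`latitude` columns.
#' @return Mean `S` over the cells containing the valid points.
#' @export
mean_mess_at_points <- function(messmap, points) {
  stopifnot(inherits(messmap, "mess_map"))
  ex <- extract_values(raster_stack(list(messmap$similarity)), points)
  s <- ex$mess_similarity[ex$valid]
  if (!length(s)) abort("All points fall outside the valid MESS cells.")
  mean(s)
}
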