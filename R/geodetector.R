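#' Jenks natural-breaks classification
#'
#' Computes the Fisher-Jenks optimal partition of the values into `L`
#' contiguous classes minimizing the total within-class sum of squared
#' deviations, and reports the `L - 1` break values. Breaks are defined
#' as the minimum value of each upper class, so that [stratify()]'s
#' lower-closed rule reproduces the optimal classes exactly.
#'
#' @param values Numeric vector (non-finite values are dropped).
#' @param L Number of classes (default 5).
#' @return Numeric vector of `L - 1` strictly ascending break values
#'   (length 0 when `L = 1`).
#' @export
#' @examples
#' jenks_breaks(c(1, 2, 10, 11), L = 2)
jenks_breaks <- function(values, L = 5) {
  x <- values[is.finite(values)]
  if (L < 1) abort("`L` must be at least 1.")
  if (L == 1) return(numeric(0))
  tab <- table(x)
  u <- as.numeric(names(tab))
  if (length(u) < L) {
    abort(sprintf("Need at least %d distinct finite values for %d classes (got %d).",
                  L, L, length(u)))
  }
  starts <- fisher_jenks_starts(u, as.numeric(tab), as.integer(L))
  u[starts + 1L]
}

#' Stratify values by break points
#'
#' Assigns stratum `h = 1 + #{breaks <= v}`: classes are half-open and
#' lower-closed, so a value equal to a break belongs to the upper class.
#'
#' @param values Numeric vector.
#' @param breaks Strictly ascending break values (possibly empty).
#' @param variable Name recorded on the result.
#' @return A `strata_map`: list with `variable`, `L`, `breaks` and the
#'   integer `assignment` (NA for non-finite values).
#' @export
stratify <- function(values, breaks, variable = "x") {
  breaks <- as.numeric(breaks)
  if (length(breaks) > 1 && any(diff(breaks) <= 0)) {
    abort("`breaks` must be strictly ascending.")
  }
  h <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  h[ok] <- 1L + as.integer(rowSums(outer(values[ok], breaks, ">=")))
  structure(list(variable = variable, L = length(breaks) + 1L,
                 breaks = breaks, assignment = h),
            class = "strata_map")
}

#' @export
print.strata_map <- function(x, ...) {
  cat(sprintf("<strata_map> %s: %d strata, breaks: %s\n", x$variable, x$L,
              paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

#' Geodetector factor detector: the q-statistic
#'
#' Measures how much of the spatial variance of a response `y` is
#' explained by a stratification: `q = 1 - SSW/SST` with
#' `SSW = sum(N_h * sigma_h^2)` and `SST = N * sigma^2`, using
#' population (divisor-N) variances so that `q = 1` exactly when strata
#' are internally constant.
#'
#' @param y Numeric response, one value per sample.
#' @param strata A [stratify()] result or an integer vector of stratum
#'   labels.
#' @return An object of class `factor_detection` with fields `variable`,
#'   `q`, `N`, `L`, per-stratum `N_h` and `sigma2_h`, `sigma2`, `SSW`,
#'   `SST` (and `p_value = NA` until [q_significance()] fills it).
#' @export
factor_q <- function(y, strata) {
  h <- if (inherits(strata, "strata_map")) strata$assignment else strata
  variable <- if (inherits(strata, "strata_map")) strata$variable else "x"
  if (length(y) != length(h)) abort("`y` and `strata` must have equal length.")
  keep <- is.finite(y) & !is.na(h)
  y <- y[keep]; h <- h[keep]
  n <- length(y)
  if (n < 2) abort("Need at least 2 valid samples.")
  pop_var <- function(v) mean((v - mean(v))^2)
  sigma2 <- pop_var(y)
  sst <- n * sigma2
  if (sst <= 0) {
    abort("Response variance is zero (constant y): q is undefined.")
  }
  groups <- split(y, h)
  n_h <- vapply(groups, length, integer(1))
  s2_h <- vapply(groups, pop_var, numeric(1))
  ssw <- sum(n_h * s2_h)
  structure(
    list(variable = variable, q = 1 - ssw / sst, p_value = NA_real_,
         N = n, L = length(groups), N_h = n_h, sigma2_h = s2_h,
         sigma2 = sigma2, SSW = ssw, SST = sst),
    class = "factor_detection"
  )
}

#' @export
print.factor_detection <- function(x, ...) {
  cat(sprintf("<factor_detection> %s: q = %.4f (N = %d, L = %d strata)",
              x$variable, x$q, x$N, x$L))
  if (is.finite(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' @export
tidy.factor_detection <- function(x, ...) {
  tibble(variable = x$variable, q = x$q, p_value = x$p_value,
         N = x$N, L = x$L, SSW = x$SSW, SST = x$SST)
}

#' Permutation significance of the q-statistic
#'
#' Permutes `y` against the stratum labels and reports
#' `p = (1 + #\{q_perm >= q_obs\}) / (n_permutations + 1)`.
#'
#' @inheritParams factor_q
#' @param n_permutations Number of label permutations (>= 99).
#' @param seed Integer seed.
#' @return The permutation p-value (scalar).
#' @export
q_significance <- function(y, strata, n_permutations = 999, seed = 1L) {
  if (n_permutations < 99) abort("Use at least 99 permutations.")
  h <- if (inherits(strata, "strata_map")) strata$assignment else strata
  keep <- is.finite(y) & !is.na(h)
  y <- y[keep]; h <- h[keep]
  obs <- factor_q(y, h)$q
  # q depends on the grouping only through group sums and sums of squares,
  # so permutations use rowsum() rather than re-splitting.
  hh <- as.integer(factor(h))
  n_h <- tabulate(hh)
  n <- length(y)
  sst <- n * mean((y - mean(y))^2)
  qs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      yp <- sample(y)
      s1 <- rowsum(yp, hh)
      s2 <- rowsum(yp^2, hh)
      1 - sum(s2 - s1^2 / n_h) / sst
    }, numeric(1))
  })
  (1 + sum(qs >= obs - 1e-12)) / (n_permutations + 1)
}

#' Build a fishnet sampling lattice over a grid
#'
#' Lays a regular lattice of points at the requested spacing (km,
#' converted to degrees using 111.32 km per degree of latitude and the
#' cosine of the grid's mean latitude for longitude), cell-centred on
#' the extent, and keeps only points falling on valid cells.
#'
#' @param spec A [grid_spec()].
#' @param spacing_km Lattice spacing in kilometres.
#' @param mask Optional logical validity matrix (e.g. from a stack);
#'   `NULL` keeps all points.
#' @return A tibble of `longitude`/`latitude` points with the spacing
#'   recorded in attribute `"spacing_km"`.
#' @export
build_fishnet <- function(spec, spacing_km = 10, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (spacing_km <= 0) abort("`spacing_km` must be positive.")
  mean_lat <- spec$y_ll + spec$n_rows * spec$cell_size / 2
  height_km <- spec$n_rows * spec$cell_size * KM_PER_DEGREE
  width_km <- spec$n_cols * spec$cell_size * KM_PER_DEGREE *
    cos(mean_lat * pi / 180)
  n_y <- floor(height_km / spacing_km + 1e-9)
  n_x <- floor(width_km / spacing_km + 1e-9)
  if (n_y < 1 || n_x < 1) {
    abort("`spacing_km` exceeds the grid extent: fewer than 1 fishnet point.")
  }
  dlat <- spacing_km / KM_PER_DEGREE
  dlon <- spacing_km / (KM_PER_DEGREE * cos(mean_lat * pi / 180))
  pts <- tidyr::expand_grid(
    latitude = spec$y_ll + (seq_len(n_y) - 0.5) * dlat,
    longitude = spec$x_ll + (seq_len(n_x) - 0.5) * dlon
  )[, c("longitude", "latitude")]
  if (!is.null(mask)) {
    rc <- point_to_cell(spec, pts$longitude, pts$latitude)
    ok <- !is.na(rc$row) & mask[cbind(rc$row, rc$col)]
    ok[is.na(ok)] <- FALSE
    pts <- pts[ok, ]
  }
  attr(pts, "spacing_km") <- spacing_km
  pts
}

#' Binary presence response at fishnet points
#'
#' `y = 1` when at least one occurrence falls inside the square fishnet
#' cell (side = spacing) centred on the point, else 0. With
#' `response = "count"` the number of occurrences is returned instead.
#'
#' @param fishnet_points A [build_fishnet()] tibble (or any tibble with
#'   longitude/latitude and a `"spacing_km"` attribute or explicit
#'   `spacing_km`).
#' @param occurrences Occurrence tibble.
#' @param spacing_km Fishnet spacing; defaults to the attribute.
#' @param response `"binary"` (default) or `"count"`.
#' @return Numeric vector, one value per fishnet point.
#' @export
presence_response <- function(fishnet_points, occurrences,
                              spacing_km = attr(fishnet_points, "spacing_km"),
                              response = c("binary", "count")) {
  response <- match.arg(response)
  if (is.null(spacing_km)) abort("`spacing_km` is required.")
  occurrences <- as_occurrences(occurrences)
  mean_lat <- mean(fishnet_points$latitude)
  half_lat <- spacing_km / 2 / KM_PER_DEGREE
  half_lon <- spacing_km / 2 / (KM_PER_DEGREE * cos(mean_lat * pi / 180))
  counts <- vapply(seq_len(nrow(fishnet_points)), function(i) {
    sum(abs(occurrences$longitude - fishnet_points$longitude[i]) <= half_lon &
        abs(occurrences$latitude - fishnet_points$latitude[i]) <= half_lat)
  }, numeric(1))
  if (response == "binary") as.numeric(counts > 0) else counts
}

#' Screen environmental variables by the geodetector q-statistic
#'
#' Runs the full factor-detector screening: builds a fishnet over the
#' stack's valid cells, derives a binary presence response from the
#' occurrences, stratifies each variable by Jenks natural breaks and
#' retains the variables whose q-statistic strictly exceeds the
#' threshold.
#'
#' @param stack A [raster_stack()] of candidate variables.
#' @param occurrences Occurrence tibble.
#' @param L Number of natural-breaks strata (default 5).
#' @param q_threshold Retention threshold; variables with
#'   `q > q_threshold` (strict) are kept. Default 0.1.
#' @param spacing_km Fishnet spacing in kilometres (default 10).
#' @param n_permutations Permutations for the significance test.
#' @param seed Integer seed.
#' @return A tibble with one row per variable: `variable`, `q`,
#'   `p_value`, `retained`, sorted by decreasing q; the retained names
#'   are also in attribute `"selected"` and the fishnet size in
#'   attribute `"n_fishnet"`.
#' @export
screen_variables <- function(stack, occurrences, L = 5, q_threshold = 0.1,
                             spacing_km = 10, n_permutations = 499,
                             seed = 1L) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!length(stack$layers)) abort("`stack` has no layers.")
  occurrences <- as_occurrences(occurrences)
  mask <- stack_valid_mask(stack)
  net <- build_fishnet(stack$spec, spacing_km, mask = mask)
  y <- presence_response(net, occurrences, spacing_km)
  x <- extract_values(stack, net)
  y <- y[x$valid]
  x <- x[x$valid, , drop = FALSE]
  res <- purrr::map_dfr(names(stack), function(v) {
    vals <- x[[v]]
    Lv <- min(L, length(unique(vals[is.finite(vals)])))
    br <- jenks_breaks(vals, Lv)
    sm <- stratify(vals, br, variable = v)
    fd <- factor_q(y, sm)
    p <- if (n_permutations >= 99) {
      q_significance(y, sm, n_permutations = n_permutations,
                     seed = as.integer(seed))
    } else {
      NA_real_  # n_permutations < 99 skips the significance test
    }
    tibble(variable = v, q = fd$q, p_value = p, L = fd$L)
  })
  res$retained <- res$q > q_threshold
  res <- dplyr::arrange(res, dplyr::desc(.data$q))
  if (!any(res$retained)) {
    warn("No variable exceeds the q threshold; selection is empty.")
  }
  attr(res, "selected") <- res$variable[res$retained]
  attr(res, "n_fishnet") <- nrow(x)
  res
}
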