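#' Define a synthetic virtual-species scenario
#'
#' A scenario fixes everything the generator needs: grid geometry, how
#' many informative ("signal") and uninformative ("noise") environmental
#' fields to draw, the true response coefficients, the occurrence sample
#' size, the future-climate perturbation and the seed. The defaults are
#' the study conditions used throughout the package's tests: a 60 x 80
#' grid, 4 signal + 3 noise variables, 200 presences, a +2 degree
#' warming and a 15% precipitation increase.
#'
#' Signal variables are split into "temperature-like" fields (carrying a
#' latitudinal gradient, shifted additively in future stacks) and
#' "precipitation-like" fields (scaled multiplicatively). The true
#' suitability is `link(b0 + sum(beta * x) + sum(gamma * x^2))` over the
#' signal variables; noise variables receive zero weight.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param x_ll,y_ll,cell_size Extent geometry in degrees.
#' @param n_noise Number of uninformative fields (`noise1`, ...).
#' @param beta Named linear coefficients of the signal variables; the
#'   names define the signal set. Names starting `temp` are treated as
#'   temperature-like, names starting `precip` as precipitation-like.
#' @param gamma Named quadratic coefficients (subset of `names(beta)`,
#'   missing entries are 0).
#' @param intercept Intercept `b0` of the linear predictor.
#' @param link `"logistic"` or `"cloglog"`.
#' @param n_presences Number of occurrence cells to draw.
#' @param warming_offset Additive shift applied to temperature-like
#'   layers in the future stack (same units as the standardized field).
#' @param precip_factor Multiplicative factor applied to
#'   precipitation-like layers in the future stack.
#' @param gradient_weight Weight of the latitudinal gradient component in
#'   temperature-like fields (0 = pure random field).
#' @param noise_weight Weight of the smoothed random-field component
#'   (0 = deterministic gradient-only fields).
#' @param smooth_sigma Gaussian smoothing radius of the random fields, in
#'   cells; 0 disables smoothing (white noise).
#' @param seed Integer seed; fully determines every generated object.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows = 60, n_cols = 80,
                               x_ll = 100, y_ll = 20, cell_size = 0.05,
                               n_noise = 3,
                               beta = c(temp1 = 3.0, temp2 = 2.5,
                                        precip1 = 3.0, precip2 = -3.0),
                               gamma = c(temp1 = -1.5),
                               intercept = -8.0,
                               link = c("logistic", "cloglog"),
                               n_presences = 200,
                               warming_offset = 2.0,
                               precip_factor = 1.15,
                               gradient_weight = 1.0,
                               noise_weight = 1.0,
                               smooth_sigma = 1,
                               seed = 1L) {
  link <- match.arg(link)
  if (n_rows < 2 || n_cols < 2) abort("Degenerate grid: need at least 2 x 2.")
  if (!length(beta)) abort("At least one signal variable is required.")
  if (is.null(names(beta)) || any(!nzchar(names(beta)))) {
    abort("`beta` must be a named vector of signal-variable coefficients.")
  }
  extra <- setdiff(names(gamma), names(beta))
  if (length(extra)) {
    abort(sprintf("`gamma` names not in `beta`: %s.",
                  paste(extra, collapse = ", ")))
  }
  g <- setNames(numeric(length(beta)), names(beta))
  g[names(gamma)] <- gamma
  spec <- grid_spec(n_rows, n_cols, x_ll, y_ll, cell_size)
  structure(
    list(spec = spec,
         signal_vars = names(beta),
         noise_vars = if (n_noise > 0) paste0("noise", seq_len(n_noise))
                      else character(),
         temp_vars = grep("^temp", names(beta), value = TRUE),
         precip_vars = grep("^precip", names(beta), value = TRUE),
         beta = beta, gamma = g, intercept = intercept, link = link,
         n_presences = as.integer(n_presences),
         warming_offset = warming_offset, precip_factor = precip_factor,
         gradient_weight = gradient_weight, noise_weight = noise_weight,
         smooth_sigma = smooth_sigma,
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %s; %d signal + %d noise vars, %d presences, seed %d\n",
    format(x$spec), length(x$signal_vars), length(x$noise_vars),
    x$n_presences, x$seed))
  invisible(x)
}

# Gaussian-kernel smoothing of a matrix by separable 1-D convolution with
# edge renormalization (kernel mass falling off the grid is dropped).
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Generate a synthetic environmental raster stack
#'
#' Each field is a weighted sum of a latitudinal gradient (temperature-like
#' layers only) and a kernel-smoothed Gaussian white-noise field, then
#' standardized to mean 0 / sd 1 over the grid. Deterministic given the
#' scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A [raster_stack()] with the scenario's signal and noise layers.
#' @export
make_environment <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  spec <- scenario$spec
  vars <- c(scenario$signal_vars, scenario$noise_vars)
  lat <- spec$y_ll + (spec$n_rows:1 - 0.5) * spec$cell_size
  # gradient decreasing with latitude, standardized over rows
  grad_col <- -(lat - mean(lat)) / stats::sd(lat)
  grad <- matrix(rep(grad_col, spec$n_cols), spec$n_rows, spec$n_cols)
  withr::with_seed(scenario$seed, {
    layers <- lapply(vars, function(v) {
      noise <- matrix(rnorm(spec$n_rows * spec$n_cols),
                      spec$n_rows, spec$n_cols)
      noise <- smooth_field(noise, scenario$smooth_sigma)
      gw <- if (v %in% scenario$temp_vars) scenario$gradient_weight else 0
      f <- gw * grad + scenario$noise_weight * noise
      s <- stats::sd(f)
      if (s > 0) f <- (f - mean(f)) / s
      units <- if (v %in% scenario$temp_vars) "std. temperature"
               else if (v %in% scenario$precip_vars) "std. precipitation"
               else "unitless"
      raster_layer(v, spec, f, units = units)
    })
  })
  raster_stack(layers)
}

link_fun <- function(eta, link) {
  switch(link,
         logistic = stats::plogis(eta),
         cloglog = 1 - exp(-exp(eta)),
         abort(sprintf("Unknown link: %s", link)))
}

#' True suitability surface of a synthetic scenario
#'
#' Computes `link(b0 + sum(beta_i x_i) + sum(gamma_i x_i^2))` cell by
#' cell over the scenario's signal variables.
#'
#' @param stack A [raster_stack()] containing the signal variables.
#' @param scenario A [synthetic_scenario()].
#' @return A [raster_layer()] named `"true_suitability"` with values in
#'   `[0, 1]`.
#' @export
make_true_suitability <- function(stack, scenario) {
  stopifnot(inherits(stack, "raster_stack"),
            inherits(scenario, "synthetic_scenario"))
  missing <- setdiff(scenario$signal_vars, names(stack))
  if (length(missing)) {
    abort(sprintf("Stack is missing signal variables: %s.",
                  paste(missing, collapse = ", ")))
  }
  eta <- matrix(scenario$intercept, stack$spec$n_rows, stack$spec$n_cols)
  for (v in scenario$signal_vars) {
    x <- stack$layers[[v]]$values
    eta <- eta + scenario$beta[[v]] * x + scenario$gamma[[v]] * x^2
  }
  raster_layer("true_suitability", stack$spec,
               link_fun(eta, scenario$link), units = "probability")
}

#' Sample virtual-species occurrences from a suitability surface
#'
#' Draws `n` distinct valid cells with probability proportional to
#' suitability (without replacement, matching the one-record-per-cell
#' deduplication applied when training) and places each point at the
#' cell centre.
#'
#' @param true_suitability A [raster_layer()] of suitabilities.
#' @param n Number of occurrence cells.
#' @param seed Integer seed.
#' @param species Species label for the returned table.
#' @return An occurrence tibble (`species`, `longitude`, `latitude`).
#' @export
sample_occurrences <- function(true_suitability, n, seed,
                               species = "virtual_species") {
  stopifnot(inherits(true_suitability, "raster_layer"))
  spec <- true_suitability$spec
  s <- true_suitability$values
  idx <- which(is.finite(s) & s > 0)
  if (!length(idx)) abort("Suitability is zero or nodata everywhere.")
  if (n > length(idx)) {
    abort(sprintf("Requested %d occurrences but only %d cells have positive suitability.",
                  n, length(idx)))
  }
  pick <- idx[withr::with_seed(
    as.integer(seed),
    sample.int(length(idx), n, replace = FALSE, prob = s[idx]))]
  rc <- arrayInd(pick, dim(s))
  tibble(
    species = species,
    longitude = spec$x_ll + (rc[, 2] - 0.5) * spec$cell_size,
    latitude = spec$y_ll + (spec$n_rows - rc[, 1] + 0.5) * spec$cell_size
  )
}

#' Build a future-scenario stack by shifting the current one
#'
#' Temperature-like layers receive the scenario's additive warming
#' offset; precipitation-like layers are scaled by the precipitation
#' factor; geometry and all other layers are unchanged.
#'
#' @param stack The current [raster_stack()].
#' @param scenario A [synthetic_scenario()].
#' @param warming_offset,precip_factor Optional overrides of the
#'   scenario's values.
#' @return A [raster_stack()] with identical geometry.
#' @export
make_future_environment <- function(stack, scenario,
                                    warming_offset = scenario$warming_offset,
                                    precip_factor = scenario$precip_factor) {
  stopifnot(inherits(stack, "raster_stack"),
            inherits(scenario, "synthetic_scenario"))
  layers <- lapply(stack$layers, function(l) {
    if (l$name %in% scenario$temp_vars) {
      l$values <- l$values + warming_offset
    } else if (l$name %in% scenario$precip_vars) {
      l$values <- l$values * precip_factor
    }
    l
  })
  raster_stack(layers)
}
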