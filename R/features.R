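# Feature construction for the maximum-entropy model.
#
# Five feature classes over raw environmental variables:
#   L linear, Q quadratic, P pairwise products, H hinge (forward and
#   reverse, K knots per variable at equispaced quantiles), T threshold
#   step indicators at the same knots.
# Linear/quadratic/product features are min-max normalized to [0, 1]
# using their training bounds; hinge and threshold features are in
# [0, 1] by construction.

FEATURE_CLASSES <- c(L = "linear", Q = "quadratic", H = "hinge",
                     P = "product", T = "threshold")

parse_fc <- function(fc) {
  letters <- strsplit(toupper(fc), "")[[1]]
  unknown <- setdiff(letters, names(FEATURE_CLASSES))
  if (length(unknown)) {
    abort(sprintf("Unknown feature-class letter(s): %s (use L, Q, H, P, T).",
                  paste(unknown, collapse = ", ")))
  }
  unname(FEATURE_CLASSES[unique(letters)])
}

#' Build model features from training samples
#'
#' Constructs the feature definitions of the requested feature classes
#' from training data (presence plus background) and evaluates them.
#'
#' @param samples Data frame or matrix of raw variable values (rows =
#'   samples, columns = variables).
#' @param fc Feature-class string, a subset of `"LQHPT"` (e.g. `"LQ"`,
#'   `"LQHPT"`).
#' @param n_knots Number of hinge/threshold knots per variable (default
#'   50), placed at equispaced quantiles of the training values.
#' @return A list with `defs` (a tibble of feature definitions: `kind`,
#'   `var1`, `var2`, `knot`, `direction`, normalization bounds `f_min`,
#'   `f_max`) and `matrix` (the evaluated training feature matrix).
#' @export
build_features <- function(samples, fc = "LQHPT", n_knots = 50) {
  kinds <- parse_fc(fc)
  x <- as.matrix(as.data.frame(samples))
  if (!all(is.finite(x))) abort("Training samples contain non-finite values.")
  vars <- colnames(x)
  if (is.null(vars)) abort("Training samples must have named columns.")

  defs <- list()
  add <- function(kind, var1, var2 = NA_character_, knot = NA_real_,
                  direction = NA_character_) {
    defs[[length(defs) + 1L]] <<- tibble(
      kind = kind, var1 = var1, var2 = var2, knot = knot,
      direction = direction, f_min = NA_real_, f_max = NA_real_)
  }

  knots_of <- function(v) {
    probs <- seq(0, 1, length.out = n_knots + 2)[-c(1, n_knots + 2)]
    unique(unname(quantile(x[, v], probs)))
  }

  for (kind in kinds) {
    if (kind == "linear") {
      for (v in vars) add("linear", v)
    } else if (kind == "quadratic") {
      for (v in vars) add("quadratic", v)
    } else if (kind == "product") {
      if (length(vars) >= 2) {
        cmb <- utils::combn(vars, 2)
        for (i in seq_len(ncol(cmb))) add("product", cmb[1, i], cmb[2, i])
      }
    } else if (kind == "hinge") {
      for (v in vars) {
        vmin <- min(x[, v]); vmax <- max(x[, v])
        for (k in knots_of(v)) {
          if (k < vmax) add("hinge", v, knot = k, direction = "forward")
          if (k > vmin) add("hinge", v, knot = k, direction = "reverse")
        }
      }
    } else if (kind == "threshold") {
      for (v in vars) {
        vmin <- min(x[, v]); vmax <- max(x[, v])
        for (k in knots_of(v)) {
          if (k > vmin && k < vmax) add("threshold", v, knot = k)
        }
      }
    }
  }
  defs <- dplyr::bind_rows(defs)
  if (!nrow(defs)) abort("No features could be constructed.")

  # raw feature values on training data fix the normalization bounds
  raw <- raw_features(defs, x)
  rng <- apply(raw, 2, range)
  norm_kind <- defs$kind %in% c("linear", "quadratic", "product")
  defs$f_min <- ifelse(norm_kind, rng[1, ], defs$f_min)
  defs$f_max <- ifelse(norm_kind, rng[2, ], defs$f_max)
  # hinge/threshold features record the variable's training bounds
  for (i in which(!norm_kind)) {
    defs$f_min[i] <- min(x[, defs$var1[i]])
    defs$f_max[i] <- max(x[, defs$var1[i]])
  }
  list(defs = defs, matrix = evaluate_features(defs, x))
}

# Un-normalized feature values (only meaningful for L/Q/P kinds; hinge
# and threshold are returned in final form).
raw_features <- function(defs, x) {
  out <- matrix(0, nrow(x), nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    xi <- x[, d$var1]
    out[, i] <- switch(d$kind,
      linear = xi,
      quadratic = xi^2,
      product = xi * x[, d$var2],
      hinge = if (d$direction == "forward") {
        pmax(0, (xi - d$knot) / (d$f_max - d$knot))
      } else {
        pmax(0, (d$knot - xi) / (d$knot - d$f_min))
      },
      threshold = as.numeric(xi > d$knot)
    )
  }
  out
}

#' Evaluate feature definitions on new data
#'
#' @param defs Feature-definition tibble from [build_features()].
#' @param newdata Data frame or matrix of raw variable values.
#' @return Numeric feature matrix (rows = samples, columns = features).
#' @export
evaluate_features <- function(defs, newdata) {
  x <- as.matrix(as.data.frame(newdata))
  missing <- setdiff(unique(c(defs$var1, defs$var2[!is.na(defs$var2)])),
                     colnames(x))
  if (length(missing)) {
    abort(sprintf("Data is missing model variable(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  out <- matrix(0, nrow(x), nrow(defs))
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    xi <- x[, d$var1]
    out[, i] <- switch(d$kind,
      linear = (xi - d$f_min) / (d$f_max - d$f_min),
      quadratic = (xi^2 - d$f_min) / (d$f_max - d$f_min),
      product = (xi * x[, d$var2] - d$f_min) / (d$f_max - d$f_min),
      hinge = if (d$direction == "forward") {
        pmax(0, (xi - d$knot) / (d$f_max - d$knot))
      } else {
        pmax(0, (d$knot - xi) / (d$knot - d$f_min))
      },
      threshold = as.numeric(xi > d$knot)
    )
  }
  colnames(out) <- feature_labels(defs)
  out
}

feature_labels <- function(defs) {
  vapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    switch(d$kind,
      linear = d$var1,
      quadratic = paste0(d$var1, "^2"),
      product = paste0(d$var1, "*", d$var2),
      hinge = sprintf("%s(%s@%.6g)",
                      if (d$direction == "forward") "hinge" else "hinge'",
                      d$var1, d$knot),
      threshold = sprintf("thr(%s@%.6g)", d$var1, d$knot))
  }, character(1))
}

# Published default L1 schedules per feature class, piecewise-linear in
# the presence count m and clamped at the schedule ends.
beta_class_default <- function(kind, m) {
  interp <- function(xs, ys) {
    if (m <= xs[1]) return(ys[1])
    if (m >= xs[length(xs)]) return(ys[length(ys)])
    stats::approx(xs, ys, xout = m)$y
  }
  switch(kind,
    linear = ,
    quadratic = ,
    product = interp(c(10, 30, 100), c(1.0, 0.2, 0.05)),
    hinge = 0.5,
    threshold = interp(c(10, 100), c(2.0, 1.0)),
    abort(sprintf("Unknown feature kind: %s", kind)))
}

# Per-feature L1 penalty beta_j = RM * beta_class(m) * sd_j / sqrt(m)
# with sd_j the presence-sample sd of the feature, floored at 1e-3 as a
# numerical guard against zero-variance features.
feature_betas <- function(defs, pres_features, rm) {
  m <- nrow(pres_features)
  sds <- pmax(apply(pres_features, 2, stats::sd), 1e-3)
  cls <- vapply(defs$kind, beta_class_default, numeric(1), m = m)
  rm * cls * sds / sqrt(m)
}
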