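#' Presence/background ROC AUC
#'
#' The Mann-Whitney statistic `P(score_presence > score_background) +
#' 0.5 * P(equal)`, computed from ranks.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(presence_scores, background_scores) {
  p <- presence_scores[is.finite(presence_scores)]
  b <- background_scores[is.finite(background_scores)]
  if (!length(p) || !length(b)) abort("Both score sets must be non-empty.")
  r <- rank(c(p, b))
  np <- length(p)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(b))
}

#' Split occurrences into training and test sets
#'
#' Holds out `round(n * test_fraction)` records (round half up) as the
#' test set, the rest as training.
#'
#' @param occurrences Occurrence tibble (or any data frame).
#' @param test_fraction Held-out fraction (default 0.25).
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_data <- function(occurrences, test_fraction = 0.25, seed = 1L) {
  occurrences <- as_tibble(occurrences)
  n <- nrow(occurrences)
  n_test <- floor(n * test_fraction + 0.5)
  if (n_test >= n && test_fraction < 1) n_test <- n - 1L
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(n, n_test, replace = FALSE))
  list(train = occurrences[setdiff(seq_len(n), idx), ],
       test = occurrences[idx, ])
}

#' Assign k-fold cross-validation folds
#'
#' @param occurrences Occurrence tibble.
#' @param k Number of folds (default 10); `k = n` gives leave-one-out.
#' @param seed Integer seed.
#' @return The tibble with an integer `fold` column; fold sizes differ
#'   by at most one and the folds partition the rows.
#' @export
cross_validate <- function(occurrences, k = 10, seed = 1L) {
  occurrences <- as_tibble(occurrences)
  n <- nrow(occurrences)
  if (k > n) abort(sprintf("Cannot make %d folds from %d records.", k, n))
  if (k < 2) abort("`k` must be at least 2.")
  fold <- withr::with_seed(as.integer(seed),
                           sample(rep_len(seq_len(k), n)))
  dplyr::mutate(occurrences, fold = fold)
}

# Map a per-feature quantity onto source variables, splitting product
# features equally between their two variables.
feature_to_variable <- function(defs, values, variables) {
  acc <- setNames(numeric(length(variables)), variables)
  for (i in seq_len(nrow(defs))) {
    if (defs$kind[i] == "product") {
      acc[defs$var1[i]] <- acc[defs$var1[i]] + values[i] / 2
      acc[defs$var2[i]] <- acc[defs$var2[i]] + values[i] / 2
    } else {
      acc[defs$var1[i]] <- acc[defs$var1[i]] + values[i]
    }
  }
  acc
}

#' Percent contribution of each variable
#'
#' Accumulates the positive training-gain increments of the fit, update
#' by update, onto each updated feature's source variable(s) (product
#' features split equally) and normalizes to 100.
#'
#' @param model A [maxent_train()] model.
#' @return A tibble `variable`, `contribution` (percent, sums to 100),
#'   sorted by decreasing contribution.
#' @export
percent_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  acc <- feature_to_variable(model$defs, model$contrib, model$variables)
  total <- sum(acc)
  if (total <= 0) {
    warn("Zero total training gain: all contributions are zero.")
    pct <- acc
  } else {
    pct <- 100 * acc / total
  }
  dplyr::arrange(tibble(variable = names(acc), contribution = unname(pct)),
                 dplyr::desc(.data$contribution))
}

#' Permutation importance of each variable
#'
#' For each variable, permutes its column jointly across the presence
#' and background samples stored in the model, recomputes the training
#' AUC, and reports the normalized AUC drop (negative drops floored at
#' zero, scaled to sum 100).
#'
#' @param model A [maxent_train()] model fitted with `keep_data = TRUE`.
#' @param seed Integer seed.
#' @param n_repeats Permutation repeats averaged per variable.
#' @return A tibble `variable`, `importance` (percent), sorted
#'   decreasing.
#' @export
permutation_importance <- function(model, seed = 1L, n_repeats = 1) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$data)) {
    abort("Model was fitted with keep_data = FALSE; raw samples unavailable.")
  }
  pres <- as.data.frame(model$data$presence)
  bg <- as.data.frame(model$data$background)
  np <- nrow(pres)
  all <- rbind(pres[, model$variables, drop = FALSE],
               bg[, model$variables, drop = FALSE])
  base_auc <- roc_auc(predict(model, pres, output = "raw"),
                      predict(model, bg, output = "raw"))
  drops <- withr::with_seed(as.integer(seed), {
    vapply(model$variables, function(v) {
      mean(vapply(seq_len(n_repeats), function(r) {
        perm <- all
        perm[[v]] <- sample(perm[[v]])
        s <- predict(model, perm, output = "raw")
        base_auc - roc_auc(s[seq_len(np)], s[-seq_len(np)])
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  total <- sum(drops)
  pct <- if (total > 0) 100 * drops / total else drops * 0
  dplyr::arrange(tibble(variable = model$variables, importance = unname(pct)),
                 dplyr::desc(.data$importance))
}

#' Jackknife variable-importance gains
#'
#' Refits the model with each variable alone and with each variable
#' excluded, reporting the regularized training gain of every fit along
#' with the full-model gain.
#'
#' @param presence,background Raw training samples (data frames with the
#'   same variable columns).
#' @param fc,rm,... Passed to [maxent_train()].
#' @param with_only_only Skip the leave-one-out refits (halves the cost
#'   when only the with-only ranking is needed)?
#' @return A tibble `variable`, `gain_only`, `gain_without`,
#'   `gain_full`.
#' @export
jackknife_gains <- function(presence, background, fc = "LQH", rm = 1,
                            with_only_only = FALSE, ...) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  vars <- colnames(background)
  if (length(vars) < 1) abort("Need at least one variable.")
  full <- maxent_train(presence, background, fc = fc, rm = rm,
                       keep_data = FALSE, ...)
  res <- purrr::map_dfr(vars, function(v) {
    only <- maxent_train(presence[, v, drop = FALSE],
                         background[, v, drop = FALSE],
                         fc = fc, rm = rm, keep_data = FALSE, ...)
    without <- if (length(vars) == 1) {
      NULL  # removing the only variable leaves the uniform model
    } else if (with_only_only) {
      NULL
    } else {
      keep <- setdiff(vars, v)
      maxent_train(presence[, keep, drop = FALSE],
                   background[, keep, drop = FALSE],
                   fc = fc, rm = rm, keep_data = FALSE, ...)
    }
    tibble(variable = v,
           gain_only = max(0, only$reg_gain),
           gain_without = if (is.null(without)) {
             if (length(vars) == 1) 0 else NA_real_
           } else max(0, without$reg_gain),
           gain_full = max(0, full$reg_gain))
  })
  res
}

#' Marginal response curve of a variable
#'
#' Sweeps one variable across its training range while holding every
#' other variable at its background mean, and records the model
#' prediction.
#'
#' @param model A [maxent_train()] model fitted with `keep_data = TRUE`.
#' @param variable Variable name.
#' @param n_grid Number of grid points (default 100).
#' @param output Prediction transform (default cloglog).
#' @return A tibble `variable`, `value`, `suitability` of class
#'   `response_curve`.
#' @export
response_curve <- function(model, variable, n_grid = 100,
                           output = c("cloglog", "logistic", "raw")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "maxent_model"))
  if (!variable %in% model$variables) {
    abort(sprintf("Unknown variable `%s`.", variable))
  }
  if (is.null(model$data)) {
    abort("Model was fitted with keep_data = FALSE; raw samples unavailable.")
  }
  i <- match(variable, model$clamp_bounds$variable)
  grid <- seq(model$clamp_bounds$min[i], model$clamp_bounds$max[i],
              length.out = n_grid)
  bg_means <- colMeans(as.data.frame(model$data$background)[model$variables])
  newdata <- as.data.frame(as.list(bg_means))[rep(1, n_grid), , drop = FALSE]
  newdata[[variable]] <- grid
  out <- tibble(variable = variable, value = grid,
                suitability = predict(model, newdata, output = output))
  class(out) <- c("response_curve", class(out))
  out
}

#' Optimal range of a response curve
#'
#' Finds the maximal sub-intervals of the swept variable where the
#' predicted suitability meets the threshold, plus the argmax.
#'
#' @param curve A [response_curve()] tibble.
#' @param threshold Suitability threshold (default 0.6, the highly
#'   suitable class).
#' @return A list with `ranges` (tibble `from`, `to`; zero rows when the
#'   curve never reaches the threshold), `argmax` and `max_suitability`.
#' @export
optimal_range <- function(curve, threshold = 0.6) {
  above <- curve$suitability >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  ranges <- tibble(from = curve$value[starts[keep]],
                   to = curve$value[ends[keep]])
  best <- which.max(curve$suitability)
  list(ranges = ranges,
       argmax = curve$value[best],
       max_suitability = curve$suitability[best])
}

#' Full model evaluation report
#'
#' Assembles training/test AUC, percent contribution, permutation
#' importance, jackknife gains and per-variable response curves with
#' their optimal ranges.
#'
#' @param model A [maxent_train()] model with stored data.
#' @param test_presence Optional held-out presence samples (raw variable
#'   values) for the test AUC.
#' @param jackknife Compute jackknife gains (refits the model 2x per
#'   variable)?
#' @param optimal_threshold Threshold for [optimal_range()].
#' @param seed Integer seed (permutation importance).
#' @return A list of class `evaluation_report`.
#' @export
evaluate_model <- function(model, test_presence = NULL, jackknife = TRUE,
                           optimal_threshold = 0.6, seed = 1L) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$data)) {
    abort("Model must be fitted with keep_data = TRUE.")
  }
  pres <- as.data.frame(model$data$presence)
  bg <- as.data.frame(model$data$background)
  sb <- predict(model, bg, output = "raw")
  train_auc <- roc_auc(predict(model, pres, output = "raw"), sb)
  test_auc <- if (!is.null(test_presence) && nrow(test_presence)) {
    roc_auc(predict(model, as.data.frame(test_presence), output = "raw"), sb)
  } else NA_real_
  curves <- purrr::map(model$variables, function(v) response_curve(model, v))
  names(curves) <- model$variables
  ranges <- purrr::map(curves, optimal_range, threshold = optimal_threshold)
  structure(
    list(train_auc = train_auc, test_auc = test_auc,
         contribution = percent_contribution(model),
         importance = permutation_importance(model, seed = seed),
         jackknife = if (jackknife) {
           jackknife_gains(pres, bg, fc = model$fc, rm = model$rm,
                           n_knots = model$n_knots)
         },
         response_curves = curves, optimal_ranges = ranges,
         optimal_threshold = optimal_threshold),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> train AUC %.3f, test AUC %s\n",
              x$train_auc,
              if (is.finite(x$test_auc)) sprintf("%.3f", x$test_auc)
              else "n/a"))
  cat("Top contributions:\n")
  print(head(x$contribution, 5))
  invisible(x)
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(train_auc = x$train_auc, test_auc = x$test_auc,
         top_variable = x$contribution$variable[1],
         top_contribution = x$contribution$contribution[1])
}
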