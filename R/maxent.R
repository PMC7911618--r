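#' Sample background cells from a raster stack
#'
#' Draws a uniform sample without replacement over the jointly valid
#' cells of the stack. When fewer valid cells exist than requested, all
#' valid cells are returned with a message.
#'
#' @param stack A [raster_stack()].
#' @param n Background sample size (default 10000).
#' @param seed Integer seed.
#' @return A tibble with `longitude`, `latitude`, `row`, `col` and one
#'   column per layer.
#' @export
sample_background <- function(stack, n = 10000, seed = 1L) {
  stopifnot(inherits(stack, "raster_stack"))
  vv <- stack_valid_values(stack)
  n_valid <- nrow(vv$values)
  if (!n_valid) abort("The stack has no valid (all-layer) cells.")
  if (n >= n_valid) {
    if (n > n_valid) {
      inform(sprintf(
        "Background request of %d capped at the %d valid cells.", n, n_valid))
    }
    pick <- seq_len(n_valid)
  } else {
    pick <- withr::with_seed(as.integer(seed),
                             sample.int(n_valid, n, replace = FALSE))
  }
  spec <- stack$spec
  out <- tibble(
    longitude = spec$x_ll + (vv$col[pick] - 0.5) * spec$cell_size,
    latitude = spec$y_ll + (spec$n_rows - vv$row[pick] + 0.5) * spec$cell_size,
    row = vv$row[pick], col = vv$col[pick]
  )
  dplyr::bind_cols(out, as_tibble(vv$values[pick, , drop = FALSE]))
}

# Core L1-penalized maximum-entropy fit by cyclic coordinate descent
# with exact soft-threshold updates and objective-guarded step halving.
# Minimizes  f(lambda) = log Z(lambda) - p . lambda + sum(beta |lambda|)
# where Z sums exp(lambda . f) over the background and p is the vector
# of presence feature means. Convergence is declared when every
# feature's KKT residual max(0, |p_j - E_j| - beta_j) drops below
# `kkt_tol`.
fit_maxent_core <- function(Fp, Fb, beta, max_iter = 500, tol = 1e-8,
                            kkt_tol = 5e-5) {
  J <- ncol(Fb)
  nb <- nrow(Fb)
  p <- colMeans(Fp)
  lambda <- numeric(J)
  w <- rep(1, nb)
  S <- nb
  log_off <- 0          # log-scale of w, for overflow protection
  pl <- 0               # p . lambda
  pen <- 0              # sum(beta * |lambda|)
  obj <- log(S)         # + log_off - pl + pen
  contrib <- numeric(J)
  obj_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  max_viol <- Inf

  while (max_iter >= 1) {
    iter <- iter + 1L
    E_all <- as.numeric(crossprod(Fb, w)) / S
    viol <- pmax(0, abs(p - E_all) - beta)
    max_viol <- max(viol)
    if (max_viol <= kkt_tol) { converged <- TRUE; break }
    active <- which(lambda != 0 | viol > kkt_tol)
    obj_before <- obj
    for (j in active) {
      fj <- Fb[, j]
      Sw <- sum(w * fj)
      E <- Sw / S
      V <- sum(w * fj * fj) / S - E^2
      V <- max(V, 1e-10)
      z <- lambda[j] * V - (E - p[j])
      l_new <- sign(z) * max(abs(z) - beta[j], 0) / V
      delta <- l_new - lambda[j]
      if (abs(delta) < 1e-13) next
      delta <- sign(delta) * min(abs(delta), 10)  # trust region
      for (half in 1:40) {
        w_new <- w * exp(delta * fj)
        S_new <- sum(w_new)
        pen_new <- pen + beta[j] * (abs(lambda[j] + delta) - abs(lambda[j]))
        obj_new <- log(S_new) - (pl + delta * p[j]) + pen_new +
          (obj - (log(S) - pl + pen))  # carry the log_off-consistent offset
        if (obj_new <= obj + 1e-12) break
        delta <- delta / 2
        if (half == 40) delta <- 0
      }
      if (delta == 0) next
      lambda[j] <- lambda[j] + delta
      w <- w_new; S <- S_new
      pl <- pl + delta * p[j]
      pen <- pen_new
      contrib[j] <- contrib[j] + max(0, obj - obj_new)
      obj <- obj_new
      if (S > 1e150 || S < 1e-150) {  # rescale to avoid overflow
        log_off <- log_off + log(S)
        w <- w / S
        S <- 1
      }
    }
    obj_trace <- c(obj_trace, obj)
    if (iter >= max_iter) break
    if (obj_before - obj < tol && max_viol <= 10 * kkt_tol) {
      # practically converged; one final KKT pass happens at loop top
    } else if (obj_before - obj < tol * 1e-3) {
      break  # no measurable progress
    }
  }

  r <- w / S
  log_z <- log(S) + log_off
  gain <- pl - (log_z - log(nb))
  E_final <- as.numeric(crossprod(Fb, w)) / S
  max_viol <- max(pmax(0, abs(p - E_final) - beta))
  list(lambda = lambda, p = p,
       E = E_final,
       beta = beta,
       log_z = log_z,
       entropy = -sum(r * log(r)),
       gain = gain,
       reg_gain = gain - pen,
       contrib = contrib,
       iterations = iter,
       converged = converged,
       max_kkt_violation = max_viol,
       obj_trace = obj_trace)
}

#' Fit a presence/background maximum-entropy model
#'
#' Fits the Gibbs distribution `p(x) proportional to exp(lambda . f(x))`
#' over the background by maximizing the L1-penalized log-likelihood of
#' the presence sample, with per-feature penalties from the published
#' class-default schedules scaled by the regularization multiplier.
#' Optimization is cyclic coordinate descent with exact soft-threshold
#' updates; the fit is declared converged when every feature satisfies
#' the KKT condition `|presence mean - model expectation| <= beta_j`
#' within `kkt_tol`.
#'
#' @param presence Data frame/matrix of raw variable values at presence
#'   samples.
#' @param background Data frame/matrix of raw variable values at
#'   background samples (same columns).
#' @param fc Feature-class string (subset of `"LQHPT"`); default
#'   `"LQHPT"`.
#' @param rm Regularization multiplier (default 1).
#' @param n_knots Hinge/threshold knots per variable (default 50).
#' @param max_iter Maximum coordinate-descent sweeps (default 500).
#' @param tol Objective-improvement tolerance per sweep.
#' @param kkt_tol KKT residual tolerance declaring convergence.
#' @param keep_data Store the raw presence/background samples in the
#'   model (needed for permutation importance and response curves)?
#' @return An object of class `maxent_model`.
#' @export
maxent_train <- function(presence, background, fc = "LQHPT", rm = 1,
                         n_knots = 50, max_iter = 500, tol = 1e-8,
                         kkt_tol = 5e-5, keep_data = TRUE) {
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  vars <- colnames(background)
  presence <- presence[, vars, drop = FALSE]
  if (nrow(presence) < 2) abort("Need at least 2 presence samples.")
  if (!nrow(background)) abort("Need background samples.")
  train <- rbind(presence, background)
  feats <- build_features(train, fc = fc, n_knots = n_knots)
  np <- nrow(presence)
  Fp <- feats$matrix[seq_len(np), , drop = FALSE]
  Fb <- feats$matrix[np + seq_len(nrow(background)), , drop = FALSE]
  beta <- feature_betas(feats$defs, Fp, rm = rm)
  fit <- fit_maxent_core(Fp, Fb, beta, max_iter = max_iter, tol = tol,
                         kkt_tol = kkt_tol)
  clamp <- tibble(
    variable = vars,
    min = unname(vapply(vars, function(v) min(train[[v]]), numeric(1))),
    max = unname(vapply(vars, function(v) max(train[[v]]), numeric(1)))
  )
  structure(
    list(defs = feats$defs, lambda = fit$lambda, beta = beta,
         fc = toupper(fc), rm = rm, n_knots = n_knots,
         variables = vars, clamp_bounds = clamp,
         log_z = fit$log_z, entropy = fit$entropy,
         gain = fit$gain, reg_gain = fit$reg_gain,
         presence_means = fit$p, bg_expectations = fit$E,
         contrib = fit$contrib,
         n_presence = nrow(presence), n_background = nrow(background),
         iterations = fit$iterations, converged = fit$converged,
         max_kkt_violation = fit$max_kkt_violation,
         obj_trace = fit$obj_trace,
         data = if (keep_data) list(presence = as_tibble(presence),
                                    background = as_tibble(background))),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    paste0("<maxent_model> FC=%s, RM=%g: %d features (%d nonzero) over %d",
           " variables\n  %d presences, %d background; gain %.4f;",
           " %s after %d sweeps (max KKT residual %.2g)\n"),
    x$fc, x$rm, length(x$lambda), sum(x$lambda != 0), length(x$variables),
    x$n_presence, x$n_background, x$gain,
    if (x$converged) "converged" else "stopped", x$iterations,
    x$max_kkt_violation))
  invisible(x)
}

#' @export
tidy.maxent_model <- function(x, ...) {
  out <- x$defs
  out$feature <- feature_labels(out)
  out$lambda <- x$lambda
  out$beta <- x$beta
  out$presence_mean <- x$presence_means
  out$model_expectation <- x$bg_expectations
  dplyr::select(out, "feature", "kind", "var1", "var2", "knot",
                "direction", "lambda", "beta", "presence_mean",
                "model_expectation")
}

#' @export
glance.maxent_model <- function(x, ...) {
  tibble(fc = x$fc, rm = x$rm,
         n_presence = x$n_presence, n_background = x$n_background,
         n_features = length(x$lambda), n_nonzero = sum(x$lambda != 0),
         gain = x$gain, reg_gain = x$reg_gain, entropy = x$entropy,
         iterations = x$iterations, converged = x$converged,
         max_kkt_violation = x$max_kkt_violation)
}

#' Predict suitability for new samples
#'
#' @param object A [maxent_train()] model.
#' @param newdata Data frame of raw variable values.
#' @param output `"cloglog"` (default), `"logistic"` or `"raw"`. Raw
#'   values are normalized against the training background (they sum to
#'   1 over it); cloglog is `1 - exp(-r * exp(H))` and logistic
#'   `r * exp(H) / (1 + r * exp(H))` with `H` the entropy of the fitted
#'   background distribution.
#' @param clamp Truncate each variable to its training range before
#'   feature evaluation (default `TRUE`)?
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 output = c("cloglog", "logistic", "raw"),
                                 clamp = TRUE, ...) {
  output <- match.arg(output)
  x <- as.data.frame(newdata)
  missing <- setdiff(object$variables, colnames(x))
  if (length(missing)) {
    abort(sprintf("`newdata` is missing variable(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  x <- x[, object$variables, drop = FALSE]
  if (clamp) {
    for (i in seq_along(object$variables)) {
      v <- object$variables[i]
      x[[v]] <- pmin(pmax(x[[v]], object$clamp_bounds$min[i]),
                     object$clamp_bounds$max[i])
    }
  }
  f <- evaluate_features(object$defs, x)
  r <- exp(as.numeric(f %*% object$lambda) - object$log_z)
  switch(output,
         raw = r,
         cloglog = 1 - exp(-r * exp(object$entropy)),
         logistic = {
           re <- r * exp(object$entropy)
           re / (1 + re)
         })
}

#' Project a fitted model onto a raster stack
#'
#' Evaluates the model on every jointly valid cell of the stack
#' (clamping each variable to its training range by default) and
#' returns a suitability raster.
#'
#' @param model A [maxent_train()] model.
#' @param stack A [raster_stack()] supplying all model variables.
#' @param clamp Clamp projection values to the training range?
#' @param output Output transform (see [predict.maxent_model()]).
#' @return A [raster_layer()] of class `suitability_map` with the
#'   transform recorded in attribute `"transform"`.
#' @export
project <- function(model, stack, clamp = TRUE,
                    output = c("cloglog", "logistic", "raw")) {
  output <- match.arg(output)
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "raster_stack"))
  missing <- setdiff(model$variables, names(stack))
  if (length(missing)) {
    abort(sprintf("Stack is missing model variable(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  vv <- stack_valid_values(stack)
  pred <- predict(model, as.data.frame(vv$values), output = output,
                  clamp = clamp)
  m <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
  m[vv$index] <- pred
  out <- raster_layer("suitability", stack$spec, m, units = output)
  class(out) <- c("suitability_map", class(out))
  attr(out, "transform") <- output
  out
}

#' Sweep the regularization multiplier and feature classes
#'
#' Fits every combination of `rm_grid` and `fc_set` on a single seeded
#' 75/25 presence split and reports training/test AUC, gain and model
#' size. No combination is selected automatically.
#'
#' @param presence Data frame of raw variable values at presence
#'   samples.
#' @param background Background data frame (same columns).
#' @param rm_grid Regularization multipliers (default 0.5 to 4 by 0.5).
#' @param fc_set Feature-class strings (default L, LQ, H, LQH, LQHP,
#'   LQHPT).
#' @param test_fraction Presence fraction held out for test AUC.
#' @param seed Integer seed for the split.
#' @param ... Passed to [maxent_train()] (e.g. `n_knots`, `max_iter`).
#' @return A tibble with one row per (rm, fc) combination.
#' @export
tune_maxent <- function(presence, background,
                        rm_grid = seq(0.5, 4, by = 0.5),
                        fc_set = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                        test_fraction = 0.25, seed = 1L, ...) {
  presence <- as.data.frame(presence)
  n <- nrow(presence)
  n_test <- floor(n * test_fraction + 0.5)
  test_idx <- withr::with_seed(as.integer(seed),
                               sample.int(n, n_test, replace = FALSE))
  ptrain <- presence[setdiff(seq_len(n), test_idx), , drop = FALSE]
  ptest <- presence[test_idx, , drop = FALSE]
  grid <- tidyr::expand_grid(rm = rm_grid, fc = fc_set)
  purrr::pmap_dfr(grid, function(rm, fc) {
    m <- maxent_train(ptrain, background, fc = fc, rm = rm,
                      keep_data = FALSE, ...)
    sb <- predict(m, background, output = "raw")
    strain <- predict(m, ptrain, output = "raw")
    stest <- if (nrow(ptest)) predict(m, ptest, output = "raw") else numeric(0)
    tibble(rm = rm, fc = fc,
           n_features = length(m$lambda), n_nonzero = sum(m$lambda != 0),
           train_auc = roc_auc(strain, sb),
           test_auc = if (length(stest)) roc_auc(stest, sb) else NA_real_,
           gain = m$gain, reg_gain = m$reg_gain)
  })
}

#' Write a fitted model as a plain-text lambdas table
#'
#' Serializes the model (header metadata, per-variable clamp bounds and
#' the feature/weight table) as a human-diffable text file that
#' [read_maxent_model()] restores to a predict-capable model.
#'
#' @param model A [maxent_train()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  hdr <- c(
    "# rangecast maxent model",
    paste("fc", model$fc),
    paste("rm", num(model$rm)),
    paste("n_knots", model$n_knots),
    paste("log_z", num(model$log_z)),
    paste("entropy", num(model$entropy)),
    paste("gain", num(model$gain)),
    paste("n_presence", model$n_presence),
    paste("n_background", model$n_background),
    "[clamps]",
    "variable\tmin\tmax",
    sprintf("%s\t%s\t%s", model$clamp_bounds$variable,
            num(model$clamp_bounds$min), num(model$clamp_bounds$max)),
    "[features]",
    "kind\tvar1\tvar2\tknot\tdirection\tf_min\tf_max\tlambda",
    sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
            model$defs$kind, model$defs$var1,
            ifelse(is.na(model$defs$var2), ".", model$defs$var2),
            ifelse(is.na(model$defs$knot), ".", num(model$defs$knot)),
            ifelse(is.na(model$defs$direction), ".", model$defs$direction),
            num(model$defs$f_min), num(model$defs$f_max),
            num(model$lambda))
  )
  writeLines(hdr, path)
  invisible(path)
}

#' Read a plain-text model written by [write_maxent_model()]
#'
#' @param path Path to the model file.
#' @return A `maxent_model` usable with [predict.maxent_model()] and
#'   [project()] (fit diagnostics that are not serialized are `NA`).
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    if (is.na(ln)) abort(sprintf("Model file is missing field `%s`.", key))
    sub(paste0("^", key, " "), "", ln)
  }
  ic <- which(lines == "[clamps]")
  if_ <- which(lines == "[features]")
  if (!length(ic) || !length(if_)) abort("Malformed model file.")
  clamp <- utils::read.delim(text = lines[(ic + 1):(if_ - 1)],
                             stringsAsFactors = FALSE)
  feats <- utils::read.delim(text = lines[(if_ + 1):length(lines)],
                             stringsAsFactors = FALSE, na.strings = ".")
  defs <- tibble(kind = feats$kind, var1 = feats$var1,
                 var2 = as.character(feats$var2),
                 knot = as.numeric(feats$knot),
                 direction = as.character(feats$direction),
                 f_min = as.numeric(feats$f_min),
                 f_max = as.numeric(feats$f_max))
  structure(
    list(defs = defs, lambda = as.numeric(feats$lambda),
         beta = rep(NA_real_, nrow(defs)),
         fc = kv("fc"), rm = as.numeric(kv("rm")),
         n_knots = as.numeric(kv("n_knots")),
         variables = clamp$variable,
         clamp_bounds = as_tibble(clamp),
         log_z = as.numeric(kv("log_z")),
         entropy = as.numeric(kv("entropy")),
         gain = as.numeric(kv("gain")),
         presence_means = rep(NA_real_, nrow(defs)),
         bg_expectations = rep(NA_real_, nrow(defs)),
         contrib = rep(NA_real_, nrow(defs)),
         n_presence = as.integer(kv("n_presence")),
         n_background = as.integer(kv("n_background")),
         iterations = NA_integer_, converged = NA,
         max_kkt_violation = NA_real_, obj_trace = numeric(0),
         data = NULL),
    class = "maxent_model"
  )
}
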