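# Independent oracles used across the suite. These deliberately use a
# different computational route than the package functions they check.

# q-statistic by direct grouped population variances (loop-based).
brute_q <- function(y, h) {
  pv <- function(v) sum((v - mean(v))^2) / length(v)
  sst <- length(y) * pv(y)
  ssw <- 0
  for (g in unique(h)) {
    yg <- y[h == g]
    ssw <- ssw + length(yg) * pv(yg)
  }
  1 - ssw / sst
}

# Exhaustive Fisher partition: all contiguous partitions of sorted
# values into L classes; returns the class assignment of the sorted
# values under the minimum within-class SSD.
jenks_exhaustive <- function(values, L) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, L - 1, simplify = FALSE)
  best <- NULL
  best_cost <- Inf
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    cost <- 0
    for (k in seq_len(L)) {
      cost <- cost + ssd(x[(bounds[k] + 1):bounds[k + 1]])
    }
    if (cost < best_cost) {
      best_cost <- cost
      best <- rep(seq_len(L), times = diff(bounds))
    }
  }
  list(assignment = best, cost = best_cost, sorted = x)
}

# Moran's I with rook contiguity, textbook formula.
morans_i_rook <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; w_sum <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; w_sum <- w_sum + 2 }
      if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; w_sum <- w_sum + 2 }
    }
  }
  (nr * nc / w_sum) * num / sum(z^2)
}

# AUC by explicit pair enumeration.
brute_auc <- function(p, b) {
  tot <- 0
  for (x in p) for (y in b) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(p) * length(b))
}

# Small helper grids/scenarios shared by tests.
tiny_layer <- function(values, name = "x", cell = 0.5, x_ll = 0, y_ll = 0,
                       nodata = -9999) {
  values <- as.matrix(values)
  spec <- grid_spec(nrow(values), ncol(values), x_ll, y_ll, cell,
                    nodata = nodata)
  raster_layer(name, spec, values)
}

small_scenario <- function(seed = 1L, ...) {
  synthetic_scenario(n_rows = 30, n_cols = 40, n_noise = 2,
                     beta = c(temp1 = 3, precip1 = 2.5),
                     gamma = c(temp1 = -1.5),
                     n_presences = 80, seed = seed, ...)
}

# A fitted model on the small scenario, cached per session.
fitted_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_scenario(seed = 42)
      st <- make_environment(sc)
      tr <- make_true_suitability(st, sc)
      occ <- sample_occurrences(tr, sc$n_presences, seed = 43)
      ex <- extract_values(st, occ)
      pres <- ex[ex$valid, names(st)]
      bg <- sample_background(st, 1200, seed = 44)[, names(st)]
      cache <<- list(
        scenario = sc, stack = st, truth = tr, occurrences = occ,
        presence = pres, background = bg,
        model = maxent_train(pres, bg, fc = "LQH", rm = 1, n_knots = 10))
    }
    cache
  }
})
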