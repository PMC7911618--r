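test_that("Jenks breaks find the optimal contiguous partition", {
  expect_equal(jenks_breaks(c(1, 2, 10, 11), L = 2), 10)
  expect_equal(jenks_breaks(c(5, 1, 3), L = 1), numeric(0))
  expect_error(jenks_breaks(c(1, 1, 2), L = 3), "distinct")

  set.seed(21)
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    L <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 2)
    if (length(unique(x)) < L) next
    oracle <- jenks_exhaustive(x, L)
    br <- jenks_breaks(x, L)
    got <- stratify(oracle$sorted, br)$assignment
    # same partition cost as the exhaustive optimum
    cost <- sum(vapply(split(oracle$sorted, got), function(v) {
      sum((v - mean(v))^2)
    }, numeric(1)))
    expect_equal(cost, oracle$cost, tolerance = 1e-10)
    expect_equal(got, oracle$assignment)
  }
})

test_that("stratification is lower-closed with boundary values going up", {
  expect_equal(stratify(c(1, 5, 9), breaks = 5)$assignment, c(1L, 2L, 2L))
  expect_equal(stratify(c(3, 8), numeric(0))$assignment, c(1L, 1L))
  expect_error(stratify(1:3, c(2, 2)), "ascending")

  # equal values always land in equal strata after jenks stratification
  set.seed(31)
  for (rep in 1:20) {
    x <- sample(round(runif(6, 0, 10)), 40, replace = TRUE)
    L <- sample(2:4, 1)
    if (length(unique(x)) < L) next
    h <- stratify(x, jenks_breaks(x, L))$assignment
    expect_true(all(tapply(h, x, function(v) length(unique(v))) == 1))
  }
})

test_that("factor_q matches the variance decomposition and its edge cases", {
  # strata-pure response explains everything
  expect_equal(factor_q(c(1, 1, 5, 5, 9), c(1, 1, 2, 2, 3))$q, 1)
  # a single stratum explains nothing
  expect_equal(factor_q(rnorm(10), rep(1, 10))$q, 0)
  # worked decomposition
  fd <- factor_q(c(0, 0, 1, 1, 1, 0), c(1, 1, 1, 2, 2, 2))
  expect_equal(fd$SST, 1.5)
  expect_equal(fd$SSW, 4 / 3)
  expect_equal(fd$q, 1 / 9)
  expect_error(factor_q(rep(2, 6), c(1, 1, 1, 2, 2, 2)), "constant")

  set.seed(41)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    y <- rnorm(n)
    h <- sample(1:sample(2:5, 1), n, replace = TRUE)
    fd <- factor_q(y, h)
    expect_equal(fd$q, brute_q(y, h), tolerance = 1e-12)
    expect_true(fd$q >= 0 && fd$q <= 1)
    # affine invariance of q
    expect_equal(factor_q(3 * y - 7, h)$q, fd$q, tolerance = 1e-12)
    # merging two strata never increases q
    if (length(unique(h)) >= 2) {
      hs <- sort(unique(h))
      h2 <- h
      h2[h2 == hs[2]] <- hs[1]
      expect_lte(factor_q(y, h2)$q, fd$q + 1e-12)
    }
  }
})

test_that("permutation p-values behave as a valid test", {
  # perfect separation reaches the permutation floor
  y <- rep(c(0, 10), each = 10)
  h <- rep(1:2, each = 10)
  expect_equal(q_significance(y, h, n_permutations = 999, seed = 1),
               1 / 1000, tolerance = 2e-3)
  # invariance to stratum relabeling
  yy <- withr::with_seed(99, rnorm(30))
  hh <- rep(1:3, 10)
  relab <- c(7L, 2L, 5L)[hh]
  expect_equal(q_significance(yy, hh, n_permutations = 199, seed = 2),
               q_significance(yy, relab, n_permutations = 199, seed = 2))
  expect_error(q_significance(rnorm(20), rep(1:2, 10),
                              n_permutations = 10), "99")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(51)
  ps <- vapply(1:200, function(i) {
    y <- rnorm(40)
    h <- sample(rep(1:4, 10))
    q_significance(y, h, n_permutations = 99, seed = i)
  }, numeric(1))
  # ~95% of null p-values should exceed 0.05 (allow binomial slack)
  expect_gt(mean(ps > 0.05), 0.90)
})

test_that("fishnet lattices have the right size and fall on valid cells", {
  # a ~100 km x 100 km extent at the equator with 10 km spacing
  cell <- 100 / 111.32 / 10          # 10 km cells in degrees
  spec <- grid_spec(10, 10, x_ll = 0, y_ll = -100 / 111.32 / 2,
                    cell_size = cell)
  net <- build_fishnet(spec, 10)
  expect_equal(nrow(net), 100)
  net1 <- build_fishnet(spec, 100)
  expect_equal(nrow(net1), 1)
  expect_error(build_fishnet(spec, 150), "fewer than 1")

  # masked cells drop their fishnet points
  mask <- matrix(TRUE, 10, 10)
  mask[, 1:5] <- FALSE
  net_m <- build_fishnet(spec, 10, mask = mask)
  expect_equal(nrow(net_m), 50)
  rc <- rangecast:::point_to_cell(spec, net_m$longitude, net_m$latitude)
  expect_true(all(mask[cbind(rc$row, rc$col)]))
})

test_that("presence response marks fishnet cells containing occurrences", {
  cell <- 10 / 111.32
  spec <- grid_spec(8, 8, 0, 0, cell)
  net <- build_fishnet(spec, 10)
  none <- presence_response(net, tibble::tibble(
    species = character(), longitude = numeric(), latitude = numeric()))
  expect_true(all(none == 0))

  at_point <- tibble::tibble(species = "sp",
                             longitude = net$longitude[5],
                             latitude = net$latitude[5])
  y <- presence_response(net, at_point)
  expect_equal(y[5], 1)
  expect_equal(sum(y), 1)

  # brute-force double loop oracle on random occurrences, count response
  set.seed(61)
  occ <- tibble::tibble(species = "sp",
                        longitude = runif(40, 0, 8 * cell),
                        latitude = runif(40, 0, 8 * cell))
  counts <- presence_response(net, occ, response = "count")
  half_lat <- 5 / 111.32
  half_lon <- 5 / (111.32 * cos(mean(net$latitude) * pi / 180))
  for (i in seq_len(nrow(net))) {
    manual <- 0
    for (j in seq_len(nrow(occ))) {
      if (abs(occ$longitude[j] - net$longitude[i]) <= half_lon &&
          abs(occ$latitude[j] - net$latitude[i]) <= half_lat) {
        manual <- manual + 1
      }
    }
    expect_equal(counts[i], manual)
  }
})

test_that("variable screening retains q above the threshold strictly", {
  sc <- small_scenario(seed = 71)
  st <- make_environment(sc)
  occ <- sample_occurrences(make_true_suitability(st, sc),
                            sc$n_presences, seed = 72)
  tab <- suppressWarnings(
    screen_variables(st, occ, n_permutations = 99, seed = 73))
  expect_setequal(tab$variable, names(st))
  expect_equal(tab$retained, tab$q > 0.1)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))

  # strict inequality: a threshold equal to an observed q drops it
  thr <- max(tab$q)
  tab2 <- suppressWarnings(
    screen_variables(st, occ, q_threshold = thr, n_permutations = 0,
                     seed = 73))
  expect_false(tab2$retained[tab2$q == thr][1])
  expect_false(thr %in% tab2$q[tab2$retained])
})
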