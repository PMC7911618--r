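test_that("background sampling is uniform, capped and seeded", {
  sc <- small_scenario(seed = 81)
  st <- make_environment(sc)
  expect_message(big <- sample_background(st, 10000, seed = 1), "capped")
  expect_equal(nrow(big), 30 * 40)
  s1 <- sample_background(st, 100, seed = 5)
  s2 <- sample_background(st, 100, seed = 5)
  expect_identical(s1, s2)

  # empirical selection frequencies on a tiny grid are uniform
  spec <- grid_spec(4, 5, 0, 0, 0.5)
  lyr <- raster_layer("x", spec, matrix(rnorm(20), 4, 5))
  stk <- raster_stack(lyr)
  hits <- integer(20)
  for (i in 1:1000) {
    b <- sample_background(stk, 5, seed = i)
    idx <- (b$col - 1) * 4 + b$row
    hits[idx] <- hits[idx] + 1
  }
  p <- 5 / 20
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(hits / 1000 - p) < 4 * se))

  empty <- raster_layer("x", spec, matrix(NA_real_, 4, 5))
  expect_error(sample_background(raster_stack(empty), 5, 1), "no valid")
})

test_that("feature construction counts and hinge geometry are correct", {
  set.seed(91)
  x <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_equal(nrow(build_features(x, "L")$defs), 3)
  expect_equal(nrow(build_features(x[, 1:2], "LQ")$defs), 4)
  expect_equal(nrow(build_features(x, "LQP")$defs), 9)
  expect_error(build_features(x, "LQZ"), "Unknown feature-class")

  fh <- build_features(x, "H", n_knots = 5)
  hmat <- fh$matrix
  expect_true(all(hmat >= 0 & hmat <= 1))
  fwd <- which(fh$defs$direction == "forward")[1]
  d <- fh$defs[fwd, ]
  xa <- x[[d$var1]]
  manual <- pmax(0, (xa - d$knot) / (d$f_max - d$knot))
  expect_equal(hmat[, fwd], manual)
  expect_equal(max(manual[xa == max(xa)]), 1)  # value 1 at training max
  expect_true(all(manual[xa <= d$knot] == 0))

  # L/Q/P features are min-max normalized on training data
  flqp <- build_features(x, "LQP")$matrix
  expect_equal(unname(apply(flqp, 2, min)), rep(0, 9))
  expect_equal(unname(apply(flqp, 2, max)), rep(1, 9))
})

test_that("an unfitted model is the uniform distribution over background", {
  sm <- fitted_small_model()
  m0 <- maxent_train(sm$presence, sm$background, fc = "LQ", max_iter = 0)
  expect_true(all(m0$lambda == 0))
  expect_equal(m0$gain, 0)
  r <- predict(m0, sm$background, output = "raw")
  expect_equal(r, rep(1 / nrow(sm$background), nrow(sm$background)))
  # uniform model cloglog is 1 - exp(-1) everywhere
  cl <- predict(m0, sm$background, output = "cloglog")
  expect_equal(unique(round(cl, 12)), round(1 - exp(-1), 12))
})

test_that("the converged fit satisfies the KKT conditions of L1 maxent", {
  sm <- fitted_small_model()
  m <- sm$model
  expect_true(m$converged)
  viol <- abs(m$presence_means - m$bg_expectations) - m$beta * 1
  expect_lt(max(viol), 1e-4)
  # penalized objective decreases monotonically across sweeps
  expect_true(all(diff(m$obj_trace) <= 1e-10))
  # raw normalization and entropy identity over the training background
  r <- predict(m, sm$background, output = "raw")
  expect_equal(sum(r), 1, tolerance = 1e-9)
  expect_equal(-sum(r * log(r)), m$entropy, tolerance = 1e-8)
})

test_that("a single binary feature recovers the closed-form weight at RM = 0", {
  set.seed(101)
  pres <- data.frame(x = rbinom(400, 1, 0.8))
  bg <- data.frame(x = rbinom(2000, 1, 0.3))
  m <- maxent_train(pres, bg, fc = "L", rm = 0, kkt_tol = 1e-10,
                    tol = 1e-14)
  pbar <- mean(pres$x)
  bbar <- mean(bg$x)
  expected <- log((pbar / (1 - pbar)) * ((1 - bbar) / bbar))
  expect_equal(m$lambda[1], expected, tolerance = 1e-6)
})

test_that("clamped projection freezes predictions beyond the training range", {
  sm <- fitted_small_model()
  m <- sm$model
  vars <- m$variables
  top <- as.data.frame(as.list(setNames(m$clamp_bounds$max, vars)))
  beyond <- top
  beyond[[1]] <- beyond[[1]] + 5
  expect_equal(predict(m, beyond, output = "cloglog"),
               predict(m, top, output = "cloglog"))
  un <- predict(m, beyond, output = "cloglog", clamp = FALSE)
  expect_false(isTRUE(all.equal(un, predict(m, top, output = "cloglog",
                                            clamp = FALSE))))

  suit <- project(m, sm$stack)
  expect_s3_class(suit, "suitability_map")
  v <- suit$values[is.finite(suit$values)]
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(attr(suit, "transform"), "cloglog")
})

test_that("the RM x FC sweep reports every combination without selecting", {
  sm <- fitted_small_model()
  pres <- sm$presence[1:40, ]
  bg <- sm$background[1:400, ]
  tab <- tune_maxent(pres, bg, seed = 3, n_knots = 4, max_iter = 60,
                     kkt_tol = 1e-3)
  expect_equal(nrow(tab), 48)
  expect_equal(nrow(dplyr::distinct(tab, rm, fc)), 48)
  expect_true(any(tab$rm == 1 & tab$fc == "LQHPT"))
  expect_true(all(tab$train_auc >= 0 & tab$train_auc <= 1))
})

test_that("stronger regularization never grows the active feature set", {
  sm <- fitted_small_model()
  pres <- sm$presence
  bg <- sm$background[1:600, ]
  nz <- vapply(c(0.5, 1, 2, 4), function(rm) {
    m <- maxent_train(pres, bg, fc = "LQ", rm = rm, kkt_tol = 1e-8,
                      tol = 1e-12)
    sum(abs(m$lambda) > 1e-8)
  }, numeric(1))
  expect_true(all(diff(nz) <= 1))  # tie tolerance of one feature
})

test_that("plain-text model files round-trip predictions exactly", {
  sm <- fitted_small_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(sm$model, path)
  back <- read_maxent_model(path)
  newd <- sm$background[1:50, ]
  expect_equal(predict(back, newd), predict(sm$model, newd),
               tolerance = 1e-12)
  expect_equal(back$fc, sm$model$fc)
  expect_equal(back$clamp_bounds$max, sm$model$clamp_bounds$max)
})
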