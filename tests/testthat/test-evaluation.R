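test_that("AUC equals pair-counting and honors the tie convention", {
  expect_equal(roc_auc(rep(1, 5), rep(0, 7)), 1)
  expect_equal(roc_auc(rep(0.3, 5), rep(0.3, 7)), 0.5)
  set.seed(111)
  for (rep in 1:25) {
    p <- sample(round(runif(sample(2:20, 1)), 1))  # rounded -> ties likely
    b <- sample(round(runif(sample(2:20, 1)), 1))
    expect_equal(roc_auc(p, b), brute_auc(p, b), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  p <- runif(15); b <- runif(25)
  expect_equal(roc_auc(exp(3 * p), exp(3 * b)), roc_auc(p, b))
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("label-independent scores give AUC near one half", {
  set.seed(121)
  aucs <- vapply(1:200, function(i) roc_auc(rnorm(30), rnorm(60)),
                 numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  expect_gt(mean(abs(aucs - 0.5) < 0.2), 0.95)
})

test_that("data splits are disjoint, exhaustive and sized by round-half-up", {
  occ <- tibble::tibble(species = "sp", longitude = runif(194),
                        latitude = runif(194))
  sp <- split_data(occ, test_fraction = 0.25, seed = 1)
  expect_equal(nrow(sp$test), 49)   # 194 * 0.25 = 48.5 rounds up
  expect_equal(nrow(sp$train), 145)
  both <- dplyr::bind_rows(sp$train, sp$test)
  expect_equal(nrow(dplyr::distinct(both)), 194)

  cv <- cross_validate(occ, k = 10, seed = 2)
  sizes <- table(cv$fold)
  expect_equal(length(sizes), 10L)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 194)
  loo <- cross_validate(occ[1:12, ], k = 12, seed = 3)
  expect_equal(sort(loo$fold), 1:12)
  expect_error(cross_validate(occ[1:5, ], k = 10), "folds")
})

test_that("percent contributions accumulate gain onto source variables", {
  sm <- fitted_small_model()
  single <- maxent_train(sm$presence[, "temp1", drop = FALSE],
                         sm$background[, "temp1", drop = FALSE],
                         fc = "LQ")
  pc1 <- percent_contribution(single)
  expect_equal(pc1$contribution, 100)

  pc <- percent_contribution(sm$model)
  expect_equal(sum(pc$contribution), 100, tolerance = 0.01)
  expect_true(all(pc$contribution >= 0))
  expect_setequal(pc$variable, sm$model$variables)

  m0 <- maxent_train(sm$presence, sm$background, fc = "L", max_iter = 0)
  expect_warning(pc0 <- percent_contribution(m0), "Zero total")
  expect_true(all(pc0$contribution == 0))
})

test_that("permutation importance ignores zero-weight variables and sums to 100", {
  sm <- fitted_small_model()
  m <- sm$model
  # zero out one variable's weights: permuting it cannot change scores
  mz <- m
  kill <- m$defs$var1 == "noise1" |
    (!is.na(m$defs$var2) & m$defs$var2 == "noise1")
  mz$lambda[kill] <- 0
  imp <- permutation_importance(mz, seed = 7)
  expect_equal(imp$importance[imp$variable == "noise1"], 0)
  expect_equal(sum(imp$importance), 100, tolerance = 0.01)
})

test_that("jackknife gains satisfy their structural identities", {
  sm <- fitted_small_model()
  jk1 <- jackknife_gains(sm$presence[, "temp1", drop = FALSE],
                         sm$background[, "temp1", drop = FALSE],
                         fc = "LQ")
  expect_equal(jk1$gain_only, jk1$gain_full, tolerance = 1e-6)
  expect_equal(jk1$gain_without, 0)

  jk <- jackknife_gains(sm$presence[, c("temp1", "precip1", "noise1")],
                        sm$background[, c("temp1", "precip1", "noise1")],
                        fc = "LQ", kkt_tol = 1e-6)
  expect_true(all(jk$gain_only >= 0))
  expect_true(all(jk$gain_without >= 0))
  # a single variable never beats the full model (regularized gain)
  expect_true(all(jk$gain_only <= jk$gain_full + 1e-4))
})

test_that("response curves expose the fitted marginal response", {
  sm <- fitted_small_model()
  # monotone single-variable linear model: optimal range abuts the max
  mono <- maxent_train(sm$presence[, "precip1", drop = FALSE],
                       sm$background[, "precip1", drop = FALSE],
                       fc = "L")
  rc <- response_curve(mono, "precip1")
  expect_true(all(diff(rc$suitability) >= -1e-12))
  thr <- stats::quantile(rc$suitability, 0.8)
  opt <- optimal_range(rc, threshold = thr)
  expect_equal(nrow(opt$ranges), 1)
  expect_equal(opt$ranges$to, max(rc$value))

  # constant curve below threshold has no optimal range
  m0 <- maxent_train(sm$presence, sm$background, fc = "L", max_iter = 0)
  rc0 <- response_curve(m0, "temp1")
  opt0 <- optimal_range(rc0, threshold = 0.9)
  expect_equal(nrow(opt0$ranges), 0)

  # interval arithmetic on a constructed bimodal curve
  fake <- tibble::tibble(variable = "v", value = seq(0, 1, by = 0.1),
                         suitability = c(0.7, 0.7, 0.2, 0.2, 0.2, 0.8,
                                         0.9, 0.8, 0.2, 0.2, 0.2))
  o <- optimal_range(fake, threshold = 0.6)
  expect_equal(o$ranges$from, c(0, 0.5))
  expect_equal(o$ranges$to, c(0.1, 0.7))
  expect_equal(o$argmax, 0.6)
})

test_that("the evaluation report assembles consistent summaries", {
  sm <- fitted_small_model()
  sp <- split_data(sm$presence, 0.25, seed = 9)
  m <- maxent_train(sp$train, sm$background, fc = "LQ")
  rep <- evaluate_model(m, test_presence = sp$test, jackknife = FALSE,
                        seed = 10)
  expect_true(rep$train_auc >= 0 && rep$train_auc <= 1)
  expect_true(rep$test_auc >= 0 && rep$test_auc <= 1)
  expect_equal(sum(rep$contribution$contribution), 100, tolerance = 0.01)
  expect_equal(sum(rep$importance$importance), 100, tolerance = 0.01)
  expect_named(rep$response_curves, m$variables, ignore.order = TRUE)
  g <- glance(rep)
  expect_equal(g$train_auc, rep$train_auc)
})
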