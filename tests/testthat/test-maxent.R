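test_that("background sampling honours bias weights and sampling bounds", {
  st <- stack_from(a = rep(1, 100), nr = 10, nc = 10)
  # uniform bias, n = all cells: every cell exactly once
  bg <- sample_background(st, n = 100, seed = 1)
  expect_setequal(bg$cell, 1:100)

  # zero bias on the southern half: nothing sampled there
  bias <- grid_from(rbind(matrix(1, 5, 10), matrix(0, 5, 10)))
  bg2 <- sample_background(st, n = 40, bias = bias, seed = 2)
  expect_true(all(bg2$y > 500))

  # 2:1 bias over equal areas: sampled ratio within 5% of 2:1
  bias3 <- grid_from(rbind(matrix(2, 5, 10), matrix(1, 5, 10)))
  bg3 <- sample_background(st, n = 10000, bias = bias3, seed = 3,
                           replace = TRUE)
  ratio <- sum(bg3$y > 500) / sum(bg3$y <= 500)
  expect_lt(abs(ratio - 2) / 2, 0.05)

  expect_error(sample_background(st, n = 101, seed = 1), "exceeds")
  zero <- grid_from(matrix(0, 10, 10))
  expect_error(sample_background(st, n = 5, bias = zero), "zero")
})

test_that("feature expansion has the documented layout and hinge behaviour", {
  set.seed(2)
  ref <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  spL <- feature_spec(ref, "L")
  expect_equal(ncol(build_features(ref, spL)), 3)
  # L + Q + P over 3 predictors: 3 + 3 + choose(3,2) = 9
  spLQP <- feature_spec(ref, "LQP")
  fm <- build_features(ref, spLQP)
  expect_equal(ncol(fm), 9)
  expect_equal(fm[, "Q:p1"], fm[, "L:p1"]^2)
  expect_equal(fm[, "P:p1*p2"], fm[, "L:p1"] * fm[, "L:p2"])

  # forward hinge is exactly zero at and below its knot
  spH <- feature_spec(ref, "H", n_knots = 4)
  x <- matrix(seq(0, 1, length.out = 11), ncol = 1,
              dimnames = list(NULL, "p1"))
  spH1 <- feature_spec(matrix(c(0, 1), ncol = 1,
                              dimnames = list(NULL, "p1")), "H", n_knots = 4)
  fh <- build_features(x, spH1)
  k <- 0.5   # a forward knot for n_knots = 4: 0, 0.25, 0.5, 0.75
  expect_true(all(fh[x <= k, "H+:p1@0.5000"] == 0))
  expect_true(all(fh[x > k, "H+:p1@0.5000"] > 0))

  expect_error(feature_spec(ref, "LX"), "unknown feature class")
})

test_that("full shrinkage and uninformative features give zero weights", {
  set.seed(3)
  bg <- matrix(runif(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  pres <- matrix(runif(60, 0.5, 1), 30, 2, dimnames = list(NULL, c("a", "b")))
  big <- fit_maxent(pres, bg, fc = "LQ", rm = 1e6)
  expect_true(all(big$lambda == 0))
  raw <- predscape:::predict_values(big, bg, "raw")
  expect_true(all(abs(raw - 1) < 1e-12))   # uniform raw prediction

  # constant predictor: its features carry no information, weight 0
  bg2 <- cbind(bg, const = 1)
  pres2 <- cbind(pres, const = 1)
  fit <- suppressWarnings(fit_maxent(pres2, bg2, fc = "LQ", rm = 0.5))
  expect_true(all(fit$lambda[grepl("const", names(fit$lambda))] == 0))

  expect_error(fit_maxent(pres[1, , drop = FALSE], bg), "two presences")
  pres_bad <- pres; pres_bad[1, 1] <- NaN
  expect_error(fit_maxent(pres_bad, bg), "non-finite")
})

test_that("single-feature fit matches a dense grid search of the objective", {
  set.seed(4)
  bg <- matrix(runif(300), ncol = 1, dimnames = list(NULL, "a"))
  pres <- matrix(rbeta(20, 4, 1.3), ncol = 1, dimnames = list(NULL, "a"))
  for (rm in c(0.5, 1, 2)) {
    fit <- suppressWarnings(
      fit_maxent(pres, bg, fc = "L", rm = rm, tol = 1e-8, max_iter = 20000))
    spec <- fit$spec
    fp <- build_features(pres, spec); fb <- build_features(bg, spec)
    pen <- rm * predscape:::penalty_weights(spec, nrow(fp))
    obj <- function(l) {
      mean(fp * l) - log(mean(exp(fb * l))) - pen * abs(l)
    }
    grid <- seq(-10, 10, by = 1e-3)
    vals <- vapply(grid, obj, numeric(1))
    expect_lt(abs(fit$lambda[[1]] - grid[which.max(vals)]), 1e-3 + 1e-3)
  }
})

test_that("two-feature fit matches a 2-D grid-search optimum", {
  set.seed(5)
  bg <- matrix(runif(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  pres <- cbind(a = rbeta(40, 3, 1.5), b = rbeta(40, 1.2, 2))
  fit <- fit_maxent(pres, bg, fc = "L", rm = 0.5, tol = 1e-8, max_iter = 20000)
  spec <- fit$spec
  fp <- build_features(pres, spec); fb <- build_features(bg, spec)
  pen <- 0.5 * predscape:::penalty_weights(spec, nrow(fp))
  obj <- function(l1, l2) {
    s <- fb %*% c(l1, l2)
    mean(fp %*% c(l1, l2)) - log(mean(exp(s))) - sum(pen * abs(c(l1, l2)))
  }
  # coarse-to-fine grid around the fitted point, plus a global coarse scan
  coarse <- expand.grid(l1 = seq(-8, 8, by = 0.25),
                        l2 = seq(-8, 8, by = 0.25))
  cv <- mapply(obj, coarse$l1, coarse$l2)
  top <- coarse[which.max(cv), ]
  fine <- expand.grid(l1 = seq(top$l1 - 0.3, top$l1 + 0.3, by = 1e-3),
                      l2 = seq(top$l2 - 0.3, top$l2 + 0.3, by = 1e-3))
  fv <- mapply(obj, fine$l1, fine$l2)
  best <- fine[which.max(fv), ]
  expect_lt(max(abs(c(fit$lambda) - c(best$l1, best$l2))), 2e-3)
})

test_that("prediction scales: normalization, logistic at tau, rank identity", {
  st <- test_stack(seed = 6, n_layers = 2)
  tr <- scenario_truth(seed = 9, extent = test_extent, cell_size = 100,
                       species_coefficients = list(sp = c(1.2, -0.4)))
  occ <- generate_occurrences(tr, st, c(sp = 80))
  bg <- sample_background(st, n = 400, seed = 10)
  pres <- predscape:::presence_values(occ, st)
  fit <- fit_maxent(pres, as.matrix(bg[, names(st)]), fc = "LQ", rm = 1)

  raw_bg <- predscape:::predict_values(fit, as.matrix(bg[, names(st)]), "raw")
  expect_lt(abs(mean(raw_bg) - 1), 1e-6)   # background mean raw = 1

  # uniform model: logistic output is exactly tau everywhere
  unif <- fit_maxent(pres, as.matrix(bg[, names(st)]), fc = "L", rm = 1e6)
  lg <- predict_suitability(unif, st, output = "logistic")
  expect_true(all(abs(lg$values - 0.5) < 1e-12, na.rm = TRUE))

  # cloglog and logistic are monotone transforms of the same raw score
  cll <- predict_suitability(fit, st, output = "cloglog")
  lgg <- predict_suitability(fit, st, output = "logistic")
  ok <- !is.na(cll$values)
  expect_equal(stats::cor(cll$values[ok], lgg$values[ok],
                          method = "spearman"), 1)
  expect_true(all(cll$values[ok] >= 0 & cll$values[ok] <= 1))

  expect_error(predict_suitability(fit, st[1], output = "cloglog"),
               "missing training predictor")
})

test_that("model JSON export records weights, scaling and normalizer", {
  set.seed(7)
  bg <- matrix(runif(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  pres <- matrix(runif(40, 0.4, 1), 20, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_maxent(pres, bg, fc = "LQ", rm = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(fit, path)
  js <- jsonlite::read_json(path)
  expect_equal(unlist(js$lambda), fit$lambda[fit$lambda != 0 | TRUE],
               tolerance = 1e-12)
  expect_equal(js$rm, 1)
  expect_equal(js$log_norm, fit$log_norm)
})
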