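test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(auc_mw(c(0.9, 0.4), c(0.5, 0.1)), 0.75)   # one discordant pair
  expect_equal(auc_mw(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_mw(rep(0.3, 5), rep(0.3, 7)), 0.5)
  set.seed(11)
  for (i in 1:5) {
    pos <- round(runif(sample(5:200, 1)), 2)   # rounding forces ties
    neg <- round(runif(sample(5:200, 1)), 2)
    expect_equal(auc_mw(pos, neg), auc_pairs(pos, neg))
  }
})

test_that("MTSS threshold matches a dense sweep; P10 uses type-7 quantile", {
  th <- compute_threshold(c(0.8, 0.9), c(0.1, 0.2), "mtss")
  expect_equal(th$value, 0.8)
  expect_equal(th$sensitivity + th$specificity, 2)   # perfect separation

  p10 <- compute_threshold(seq(0.1, 1.0, by = 0.1), c(0.5), "p10")
  expect_equal(p10$value, 0.19)

  set.seed(12)
  for (i in 1:5) {
    pres <- runif(40); bg <- runif(150)
    got <- compute_threshold(pres, bg, "mtss")
    dense <- seq(0, 1, by = 1e-3)
    obj <- function(t) mean(pres >= t) + mean(bg < t)
    # the optimum is attained at a score value, so the candidate scan must
    # match a sweep that includes them and never lose to the dense grid
    expect_equal(got$sensitivity + got$specificity,
                 max(vapply(c(dense, pres, bg), obj, numeric(1))),
                 tolerance = 1e-9)
    expect_gte(got$sensitivity + got$specificity,
               max(vapply(dense, obj, numeric(1))) - 1e-9)
  }
})

test_that("AICc formula arithmetic and degenerate cases", {
  expect_equal(predscape:::aicc_formula(K = 2, n = 10, lnL = -5),
               2 * 2 + 10 + 12 / 7)
  expect_equal(predscape:::aicc_formula(2, 10, -5), 15.714286,
               tolerance = 1e-6)
  # equal likelihood: fewer parameters wins
  expect_lt(predscape:::aicc_formula(1, 30, -10),
            predscape:::aicc_formula(3, 30, -10))
  expect_equal(predscape:::aicc_formula(5, 6, -1), Inf)
})

test_that("binarization respects the >= convention and propagates NA", {
  m <- matrix(c(0.1, 0.406, 0.9, NA), 2, 2)
  g <- grid_from(m)
  b0 <- binarize_map(g, 0)
  expect_true(all(b0$values[!is.na(m)] == 1))
  bhi <- binarize_map(g, 0.95)
  expect_true(all(bhi$values[!is.na(m)] == 0))
  bt <- binarize_map(g, 0.406)
  expect_equal(bt$values[is.na(m) == FALSE], c(0, 1, 1))  # 0.406 -> suitable
  expect_true(is.na(bt$values[is.na(m)]))
  u <- grid_from(matrix(0.406, 3, 3))
  expect_true(all(binarize_map(u, 0.406)$values == 1))
})

test_that("cross-validation folds, metrics and config errors behave", {
  st <- test_stack(seed = 13, n_layers = 2)
  tr <- scenario_truth(seed = 14, extent = test_extent, cell_size = 100,
                       species_coefficients = list(sp = c(1.5, 0.5)))
  occ <- generate_occurrences(tr, st, c(sp = 60))
  bg <- sample_background(st, n = 300, seed = 15)
  ev <- cv_evaluate(occ, st, bg, fc = "L", rm = 1, k = 5, seed = 16)
  expect_equal(nrow(ev$folds), 5)
  expect_true(all(ev$folds$train_auc >= 0 & ev$folds$train_auc <= 1))
  expect_true(all(ev$folds$test_auc >= 0 & ev$folds$test_auc <= 1))
  expect_true(all(ev$folds$omission >= 0 & ev$folds$omission <= 1))
  expect_gt(ev$mean_test_auc, 0.5)   # informative layer beats chance
  expect_true(is.finite(ev$aicc))
  # fold sizes differ by at most one
  sizes <- lengths(predscape:::make_folds(60, 7, 1))
  expect_lte(diff(range(sizes)), 1)
  expect_error(cv_evaluate(occ, st, bg, k = 1), "k must be")
  few <- occ[1:3, ]
  expect_error(cv_evaluate(predscape:::presence_values(few, st), st, bg,
                           k = 5), "fewer presences")
})

test_that("model tuning ranks by AICc with omission/AUC tie-breaking", {
  st <- test_stack(seed = 17, n_layers = 2)
  tr <- scenario_truth(seed = 18, extent = test_extent, cell_size = 100,
                       species_coefficients = list(sp = c(1.5, -0.5)))
  occ <- generate_occurrences(tr, st, c(sp = 50))
  bg <- sample_background(st, n = 200, seed = 19)

  single <- tune_model(occ, st, bg, rm_grid = 1, fc_grid = "L", k = 3,
                       seed = 20)
  expect_equal(single$best$rm, 1)
  expect_equal(single$best$fc, "L")
  expect_equal(nrow(single$table), 1)

  # duplicate configs: deterministic first-listed winner
  dup <- tune_model(occ, st, bg, rm_grid = 1, fc_grid = c("L", "L"),
                    k = 3, seed = 20)
  expect_equal(nrow(dup$table), 2)
  expect_equal(dup$best$fc, "L")

  # a 2x3 grid emits one row per configuration, ranked by delta AICc
  tg <- tune_model(occ, st, bg, rm_grid = c(1, 2), fc_grid = c("L", "LQ", "H"),
                   k = 3, seed = 20, max_iter = 200, n_knots = 6)
  expect_equal(nrow(tg$table), 6)
  expect_equal(tg$table$delta_aicc[1], 0)
  expect_true(!is.unsorted(tg$table$delta_aicc))
})

test_that("importance diagnostics normalize and respect symmetry", {
  st <- test_stack(seed = 21, n_layers = 2)
  tr <- scenario_truth(seed = 22, extent = test_extent, cell_size = 100,
                       species_coefficients = list(sp = c(2, 0)))
  occ <- generate_occurrences(tr, st, c(sp = 80))
  bg <- sample_background(st, n = 300, seed = 23)
  pres <- predscape:::presence_values(occ, st)
  fit <- fit_maxent(pres, as.matrix(bg[, names(st)]), fc = "L", rm = 0.5)
  imp <- importance_suite(fit, pres, st, n_permutations = 3, seed = 24)
  expect_equal(sum(imp$percent_contribution), 100, tolerance = 1e-6)
  expect_equal(sum(imp$permutation_importance), 100, tolerance = 1e-6)
  # the informative layer dominates both measures
  expect_gt(imp$percent_contribution[imp$variable == "env1"], 50)
  expect_gt(imp$permutation_importance[imp$variable == "env1"], 50)

  # duplicated informative variable: symmetric jackknife, redundant "without"
  st2 <- c(st["env1"], list(copy = st$env1))
  st2$copy$name <- "copy"
  pres2 <- predscape:::presence_values(occ, st2)
  bg2 <- sample_background(st2, n = 300, seed = 23)
  fit2 <- fit_maxent(pres2, as.matrix(bg2[, names(st2)]), fc = "L", rm = 0.5)
  imp2 <- importance_suite(fit2, pres2, st2, n_permutations = 3, seed = 25)
  expect_equal(imp2$jackknife_only_gain[1], imp2$jackknife_only_gain[2],
               tolerance = 1e-3)
  full_gain <- predscape:::maxent_gain(
    fit2$lambda,
    build_features(pres2, fit2$spec),
    build_features(as.matrix(bg2[, names(st2)]), fit2$spec))
  expect_equal(imp2$jackknife_without_gain[1], full_gain, tolerance = 1e-2)

  # single-variable model: permutation importance 100 by convention
  fit1 <- fit_maxent(pres2[, "env1", drop = FALSE],
                     as.matrix(bg2[, "env1", drop = FALSE]), fc = "L",
                     rm = 0.5)
  imp1 <- importance_suite(fit1, pres2[, "env1", drop = FALSE], st2["env1"],
                           n_permutations = 2, seed = 26)
  expect_equal(imp1$permutation_importance, 100)
})

test_that("response curves reflect the fitted relationship", {
  set.seed(27)
  bg <- matrix(runif(600), 300, 2, dimnames = list(NULL, c("a", "b")))
  pres <- cbind(a = rbeta(50, 4, 1.2), b = runif(50))
  fit <- fit_maxent(pres, bg, fc = "L", rm = 0.5)
  rc <- response_curve(fit, "a", n_points = 50)
  expect_equal(nrow(rc), 50)
  expect_equal(range(rc$value), c(min(bg[, "a"]), max(bg[, "a"])))
  expect_true(all(diff(rc$suitability) >= -1e-12))   # monotone increasing

  unif <- fit_maxent(pres, bg, fc = "L", rm = 1e6)
  flat <- response_curve(unif, "b", n_points = 20)
  expect_lt(diff(range(flat$suitability)), 1e-12)
  expect_error(response_curve(fit, "zzz"), "unknown variable")
})

test_that("synthetic occurrences recover the sign of every coefficient", {
  # linear-features fit on generator output: signed effects recovered in
  # at least 95% of seeded replicates
  n_rep <- 20
  beta <- c(1.2, -0.8)
  hits <- vapply(seq_len(n_rep), function(i) {
    st <- generate_predictor_stack(seed = 100 + i, extent = test_extent,
                                   cell_size = 100, n_layers = 2)
    tr <- scenario_truth(seed = 200 + i, extent = test_extent,
                         cell_size = 100,
                         species_coefficients = list(sp = beta))
    occ <- generate_occurrences(tr, st, c(sp = 500))
    bg <- sample_background(st, n = 1000, seed = 300 + i)
    pres <- predscape:::presence_values(occ, st)
    fit <- suppressWarnings(
      fit_maxent(pres, as.matrix(bg[, names(st)]), fc = "L", rm = 0.5))
    all(sign(fit$lambda) == sign(beta))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
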