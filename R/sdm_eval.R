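#' AUC by the Mann-Whitney statistic
#'
#' Probability that a random presence scores above a random background
#' point; ties count one half. Rank-based, equivalent to exhaustive pair
#' counting.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Suitability thresholds: MTSS and 10th-percentile training presence
#'
#' MTSS scans every unique predicted value as a candidate cutoff and picks
#' the one maximizing sensitivity (presences with prediction >= cutoff) plus
#' specificity (background below cutoff); ties resolve to the smallest
#' cutoff. P10 is the 10th percentile of the presence scores (linear
#' interpolation, type-7 quantile).
#'
#' @param presence_scores,background_scores Numeric score vectors
#'   (training predictions).
#' @param method `"mtss"` or `"p10"`.
#' @return One-row tibble: `method`, `value`, `sensitivity`, `specificity`.
#' @export
compute_threshold <- function(presence_scores, background_scores,
                              method = c("mtss", "p10")) {
  method <- match.arg(method)
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  if (method == "p10") {
    thr <- unname(stats::quantile(presence_scores, 0.10, type = 7))
  } else {
    cand <- sort(unique(c(presence_scores, background_scores)))
    sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
    spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
    best <- which.max(sens + spec)   # which.max -> first (smallest) on ties
    thr <- cand[best]
  }
  tibble::tibble(
    method = method, value = thr,
    sensitivity = mean(presence_scores >= thr),
    specificity = mean(background_scores < thr)
  )
}

#' Binarize a suitability map at a threshold
#'
#' Cells with value >= threshold become 1 (suitable), below become 0;
#' `NA` cells stay `NA`.
#'
#' @param suit A suitability `raster_grid`.
#' @param threshold Cutoff in [0, 1].
#' @return A `raster_grid` of 0/1.
#' @export
binarize_map <- function(suit, threshold) {
  stopifnot(inherits(suit, "raster_grid"),
            threshold >= 0, threshold <= 1)
  m <- (suit$values >= threshold) * 1
  raster_grid(m, suit$xmin, suit$ymin, suit$cell_size, crs = suit$crs,
              name = paste0(suit$name, "_bin"))
}

# predictor values at occurrence points (nearest cell), complete rows only
presence_values <- function(occ, stack) {
  stack <- check_stack(stack)
  vals <- vapply(stack, function(g) raster_extract(g, occ$x, occ$y),
                 numeric(nrow(occ)))
  vals <- matrix(vals, nrow = nrow(occ),
                 dimnames = list(NULL, names(stack)))
  vals[stats::complete.cases(vals), , drop = FALSE]
}

# seeded k folds differing by at most one in size
make_folds <- function(n, k, seed) {
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(n)
  })
  fold <- rep(seq_len(k), length.out = n)
  stats::setNames(fold[order(idx)], NULL)
  split(idx, fold)
}

#' Cross-validated evaluation of a maxent configuration
#'
#' Presences are randomly split into k near-equal folds (seeded shuffle).
#' Each fold in turn is held out: the model is fitted on the remaining
#' presences, and the held-out fold scored against the background sample
#' (test AUC) and against the training MTSS threshold (omission rate =
#' share of test presences below it). The full-data fit supplies AICc and
#' the nonzero-weight count.
#'
#' @param occ An `occurrence_set` (one species) or matrix of presence
#'   predictor values.
#' @param stack Predictor stack.
#' @param background Background tibble from [sample_background()].
#' @param fc,rm Feature classes and regularization multiplier.
#' @param k Folds (>= 2; must not exceed the presence count).
#' @param seed Integer seed for fold assignment.
#' @param ... Passed to [fit_maxent()].
#' @return An `eval_report`: `folds` tibble (train/test AUC, omission),
#'   summary means/sds, `aicc`, `n_parameters`, and the full-data model.
#' @export
cv_evaluate <- function(occ, stack, background, fc = "LQH", rm = 1, k = 5,
                        seed = 1L, ...) {
  stack <- check_stack(stack)
  pres <- if (inherits(occ, "occurrence_set")) presence_values(occ, stack)
          else as.matrix(occ)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (nrow(pres) < k) stop("fewer presences than folds", call. = FALSE)
  bg <- as.matrix(background[, names(stack), drop = FALSE])
  folds <- make_folds(nrow(pres), k, seed)
  rows <- purrr::imap_dfr(folds, function(test_idx, fi) {
    train <- pres[-test_idx, , drop = FALSE]
    test <- pres[test_idx, , drop = FALSE]
    fit <- suppressWarnings(fit_maxent(train, bg, fc = fc, rm = rm, ...))
    str_ <- predict_values(fit, train, output = "raw")
    sb <- predict_values(fit, bg, output = "raw")
    ste <- predict_values(fit, test, output = "raw")
    thr <- compute_threshold(str_, sb, method = "mtss")$value
    tibble::tibble(
      fold = as.integer(fi),
      train_auc = auc_mw(str_, sb),
      test_auc = auc_mw(ste, sb),
      omission = mean(ste < thr)
    )
  })
  full <- suppressWarnings(fit_maxent(pres, bg, fc = fc, rm = rm, ...))
  structure(
    list(folds = rows,
         mean_train_auc = mean(rows$train_auc),
         sd_train_auc = stats::sd(rows$train_auc),
         mean_test_auc = mean(rows$test_auc),
         sd_test_auc = stats::sd(rows$test_auc),
         mean_omission = mean(rows$omission),
         aicc = aicc_score(full, pres, stack),
         n_parameters = sum(full$lambda != 0),
         model = full, fc = fc, rm = rm, k = k, seed = as.integer(seed)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> FC=%s RM=%g, %d-fold CV\n", x$fc, x$rm, x$k))
  cat(sprintf("  train AUC %.3f +/- %.4f; test AUC %.3f +/- %.4f\n",
              x$mean_train_auc, x$sd_train_auc,
              x$mean_test_auc, x$sd_test_auc))
  cat(sprintf("  mean omission %.3f; AICc %.2f (K=%d)\n",
              x$mean_omission, x$aicc, x$n_parameters))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$folds

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(fc = x$fc, rm = x$rm, k = x$k,
                 mean_train_auc = x$mean_train_auc,
                 sd_train_auc = x$sd_train_auc,
                 mean_test_auc = x$mean_test_auc,
                 sd_test_auc = x$sd_test_auc,
                 mean_omission = x$mean_omission,
                 aicc = x$aicc, n_parameters = x$n_parameters)
}

#' Small-sample AIC of a fitted maxent model
#'
#' The likelihood treats the landscape raw prediction, normalized to sum 1
#' over valid cells, as the probability of each presence cell:
#' `lnL = sum_i log(raw_i / sum_cells raw)`. K counts nonzero weights.
#' `AICc = 2K - 2 lnL + 2K(K+1)/(n-K-1)`; undefined (reported `+Inf` with a
#' warning) when `n <= K + 1`, so such a model cannot win selection.
#'
#' @param model A `maxent_model`.
#' @param presence Presence predictor values (matrix) or `occurrence_set`.
#' @param stack Predictor stack defining the landscape cells.
#' @return AICc (scalar).
#' @export
aicc_score <- function(model, presence, stack) {
  stack <- check_stack(stack)
  pres <- if (inherits(presence, "occurrence_set")) {
    presence_values(presence, stack)
  } else as.matrix(presence)
  n <- nrow(pres)
  K <- sum(model$lambda != 0)
  if (n <= K + 1) {
    warning("AICc undefined: n <= K + 1; reporting +Inf")
    return(Inf)
  }
  vals <- stack_values(stack)[, model$spec$vars, drop = FALSE]
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  raw_cells <- predict_values(model, vals, output = "raw")
  raw_pres <- predict_values(model, pres, output = "raw")
  lnL <- sum(log(raw_pres / sum(raw_cells)))
  aicc_formula(K, n, lnL)
}

# AICc = 2K - 2 lnL + 2K(K+1)/(n - K - 1)
aicc_formula <- function(K, n, lnL) {
  if (n <= K + 1) return(Inf)
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}

#' Tune regularization multiplier and feature classes by AICc
#'
#' Fits every combination of `rm_grid` x `fc_grid` with k-fold
#' cross-validation, ranks by AICc, and breaks near-ties (delta AICc < 2)
#' by lower mean test omission, then higher mean test AUC, then listing
#' order. The default grid follows the standard tuning design: RM 0.5-4 in
#' steps of 0.5 against the feature combinations L, LQ, H, LQH, LQHP.
#'
#' @param occ Presences (`occurrence_set` or value matrix).
#' @param stack Predictor stack.
#' @param background Background tibble.
#' @param rm_grid Regularization multipliers.
#' @param fc_grid Character vector of feature-class strings.
#' @param k,seed Cross-validation folds and seed.
#' @param ... Passed to [fit_maxent()].
#' @return A `tune_result`: `best` (list `rm`, `fc`, the winning
#'   `eval_report`) and `table` (one row per grid cell).
#' @export
tune_model <- function(occ, stack, background,
                       rm_grid = seq(0.5, 4, by = 0.5),
                       fc_grid = c("L", "LQ", "H", "LQH", "LQHP"),
                       k = 5, seed = 1L, ...) {
  stopifnot(length(rm_grid) > 0, length(fc_grid) > 0)
  grid <- tidyr::expand_grid(fc = fc_grid, rm = rm_grid)
  reports <- purrr::pmap(grid, function(fc, rm) {
    tryCatch(
      suppressWarnings(cv_evaluate(occ, stack, background, fc = fc, rm = rm,
                                   k = k, seed = seed, ...)),
      error = function(e) NULL)
  })
  ok <- !vapply(reports, is.null, logical(1))
  if (!any(ok)) stop("all grid cells failed to fit", call. = FALSE)
  tab <- purrr::map_dfr(reports[ok], glance)
  tab$order <- seq_len(nrow(tab))
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  tied <- which(tab$delta_aicc < 2)
  pick <- tied[order(tab$mean_omission[tied], -tab$mean_test_auc[tied],
                     tab$order[tied])][1]
  tab <- dplyr::arrange(tab, .data$delta_aicc, .data$mean_omission,
                        dplyr::desc(.data$mean_test_auc), .data$order)
  structure(
    list(best = list(rm = tab$rm[tab$order == pick][1],
                     fc = tab$fc[tab$order == pick][1],
                     report = reports[ok][[pick]]),
         table = dplyr::select(tab, -"order")),
    class = "tune_result"
  )
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> %d configurations; best FC=%s RM=%g (AICc %.2f)\n",
              nrow(x$table), x$best$fc, x$best$rm, x$best$report$aicc))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
tidy.tune_result <- function(x, ...) x$table

#' Variable-importance diagnostics for a fitted model
#'
#' Three complementary views per predictor:
#' * **Permutation importance**: the variable's values are permuted over
#'   the evaluation cells (presences + background) and the drop in training
#'   AUC recorded; drops are clamped at zero and normalized to sum 100.
#' * **Percent contribution**: sum over the variable's features of
#'   `|weight| * feature sd over background`, normalized to sum 100. This
#'   is a path-independent surrogate for the contribution tracked during
#'   training by the original maxent software, and is not numerically
#'   identical to it; product features credit both participating variables.
#' * **Jackknife**: the model is refitted with only this variable and
#'   without it; the training gain (unpenalized maxent objective) of each
#'   refit is reported.
#'
#' @param model A `maxent_model`.
#' @param presence Presence predictor values (matrix or `occurrence_set`).
#' @param stack Predictor stack (needed when `presence` is an
#'   `occurrence_set`, and for variable names).
#' @param n_permutations Permutation rounds per variable (default 5).
#' @param seed Integer seed.
#' @return Tibble: `variable`, `percent_contribution`,
#'   `permutation_importance`, `jackknife_only_gain`,
#'   `jackknife_without_gain`.
#' @export
importance_suite <- function(model, presence, stack, n_permutations = 5,
                             seed = 1L) {
  stopifnot(inherits(model, "maxent_model"))
  stack <- check_stack(stack)
  pres <- if (inherits(presence, "occurrence_set")) {
    presence_values(presence, stack)
  } else as.matrix(presence)
  pres <- pres[, model$spec$vars, drop = FALSE]
  bg <- model$background[, model$spec$vars, drop = FALSE]
  vars <- model$spec$vars

  # percent contribution: |weight| x background feature sd, per variable
  fb <- build_features(bg, model$spec)
  sds <- apply(fb, 2, stats::sd)
  contrib_feat <- abs(model$lambda) * sds
  contrib <- vapply(vars, function(v) {
    own <- model$spec$feature_var == v |
      grepl(paste0("(^|\\*)", v, "($|\\*)"), model$spec$feature_var)
    sum(contrib_feat[own])
  }, numeric(1))
  contrib <- if (sum(contrib) > 0) 100 * contrib / sum(contrib)
             else rep(0, length(vars))

  # permutation importance: AUC drop when one variable is shuffled
  full_auc <- auc_mw(predict_values(model, pres, "raw"),
                     predict_values(model, bg, "raw"))
  all_vals <- rbind(pres, bg)
  is_pres <- c(rep(TRUE, nrow(pres)), rep(FALSE, nrow(bg)))
  drops <- withr::with_seed(as.integer(seed), {
    vapply(vars, function(v) {
      mean(vapply(seq_len(n_permutations), function(i) {
        perm <- all_vals
        perm[, v] <- sample(perm[, v])
        sc <- predict_values(model, perm, "raw")
        full_auc - auc_mw(sc[is_pres], sc[!is_pres])
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  perm_imp <- if (length(vars) == 1L) {
    stats::setNames(100, vars)         # single-variable convention
  } else if (sum(drops) > 0) {
    100 * drops / sum(drops)
  } else stats::setNames(rep(0, length(vars)), vars)

  # jackknife: refit with only / without each variable
  fc <- paste(model$spec$classes, collapse = "")
  jk <- purrr::map_dfr(vars, function(v) {
    only <- suppressWarnings(
      fit_maxent(pres[, v, drop = FALSE], bg[, v, drop = FALSE],
                 fc = fc, rm = model$rm, n_knots = model$spec$n_knots))
    without_gain <- if (length(vars) > 1L) {
      rest <- setdiff(vars, v)
      wo <- suppressWarnings(
        fit_maxent(pres[, rest, drop = FALSE], bg[, rest, drop = FALSE],
                   fc = fc, rm = model$rm, n_knots = model$spec$n_knots))
      maxent_gain(wo$lambda, build_features(pres[, rest, drop = FALSE], wo$spec),
                  build_features(bg[, rest, drop = FALSE], wo$spec))
    } else NA_real_
    tibble::tibble(
      variable = v,
      jackknife_only_gain = maxent_gain(
        only$lambda, build_features(pres[, v, drop = FALSE], only$spec),
        build_features(bg[, v, drop = FALSE], only$spec)),
      jackknife_without_gain = without_gain
    )
  })
  tibble::tibble(variable = vars,
                 percent_contribution = unname(contrib),
                 permutation_importance = unname(perm_imp)) |>
    dplyr::left_join(jk, by = "variable")
}

#' Response curve of one predictor
#'
#' The predictor is swept over its observed (training) range at `n_points`
#' values while all other predictors sit at their background means; the
#' cloglog prediction is returned.
#'
#' @param model A `maxent_model`.
#' @param variable Predictor name.
#' @param n_points Number of evaluation points (rows returned).
#' @param output Prediction scale (default `"cloglog"`).
#' @return Tibble with `variable`, `value`, `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 100,
                           output = "cloglog") {
  stopifnot(inherits(model, "maxent_model"))
  if (!variable %in% model$spec$vars) {
    stop("unknown variable: ", variable, call. = FALSE)
  }
  bg <- model$background[, model$spec$vars, drop = FALSE]
  xs <- seq(model$spec$mins[[variable]], model$spec$maxs[[variable]],
            length.out = n_points)
  grid <- matrix(rep(colMeans(bg), each = n_points), nrow = n_points,
                 dimnames = list(NULL, model$spec$vars))
  grid[, variable] <- xs
  tibble::tibble(variable = variable, value = xs,
                 suitability = predict_values(model, grid, output))
}

#' Plot response curves
#'
#' @param model A `maxent_model`.
#' @param variables Predictors to sweep (default all).
#' @param n_points Points per curve.
#' @export
plot_response_curves <- function(model, variables = model$spec$vars,
                                 n_points = 100) {
  df <- purrr::map_dfr(variables, response_curve, model = model,
                       n_points = n_points)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$suitability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = "Predictor value", y = "Suitability (cloglog)") +
    ggplot2::theme_minimal()
}
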