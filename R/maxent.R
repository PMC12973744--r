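#' Sample background cells, optionally weighted by a bias layer
#'
#' Background (pseudo-absence) cells are drawn from the valid cells of the
#' stack with probability proportional to the bias layer value (uniform
#' when no bias is supplied), without replacement by default.
#'
#' @param stack Predictor stack.
#' @param n Number of background points (default 10,000, capped at the
#'   number of valid cells when sampling without replacement).
#' @param bias Optional `raster_grid` of nonnegative weights on the same
#'   geometry; must not be all zero.
#' @param seed Integer seed.
#' @param replace Sample with replacement (default `FALSE`).
#' @return Tibble with `x`, `y`, `cell`, and one column per stack layer.
#' @export
sample_background <- function(stack, n = 10000, bias = NULL, seed = 1L,
                              replace = FALSE) {
  stack <- check_stack(stack)
  vals <- stack_values(stack)
  xy <- raster_xy(stack[[1]])
  valid <- which(stats::complete.cases(vals))
  if (!is.null(bias)) {
    if (!same_geometry(bias, stack[[1]])) {
      stop("bias layer geometry does not match the stack", call. = FALSE)
    }
    w <- raster_values(bias)[valid]
    w[is.na(w)] <- 0
    if (all(w == 0)) stop("bias layer is zero everywhere", call. = FALSE)
  } else {
    w <- rep(1, length(valid))
  }
  if (!replace && n > length(valid)) {
    stop("n exceeds the number of valid cells; use replace = TRUE",
         call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    pick <- valid[sample.int(length(valid), n, replace = replace, prob = w)]
  })
  out <- tibble::tibble(x = xy$x[pick], y = xy$y[pick], cell = pick)
  dplyr::bind_cols(out, tibble::as_tibble(vals[pick, , drop = FALSE]))
}

# canonical class order for deterministic feature layout
FC_ORDER <- c("L", "Q", "H", "P")

parse_fc <- function(fc) {
  letters <- unique(strsplit(toupper(fc), "")[[1]])
  bad <- setdiff(letters, FC_ORDER)
  if (length(bad)) {
    stop("unknown feature class letter(s): ", paste(bad, collapse = ""),
         " (supported: L, Q, H, P)", call. = FALSE)
  }
  FC_ORDER[FC_ORDER %in% letters]
}

#' Define a feature expansion over a predictor set
#'
#' Stores per-predictor min/max scaling (taken from the supplied reference
#' values, normally the background sample) and the feature layout for a
#' feature-class combination: linear (L) identity features, quadratic (Q)
#' squares, product (P) all pairwise products, hinge (H) forward and
#' reverse hinges at `n_knots` evenly spaced knots per predictor. Feature
#' order is deterministic (classes in L, Q, H, P order, predictors in
#' column order, knots ascending).
#'
#' @param reference Numeric matrix of predictor values (rows = samples)
#'   whose column ranges define the [0,1] standardization.
#' @param fc Feature-class string, e.g. `"LQH"`.
#' @param n_knots Hinge knots per predictor (default 20).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(reference, fc = "LQH", n_knots = 20) {
  classes <- parse_fc(fc)
  reference <- as.matrix(reference)
  vars <- colnames(reference)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(reference)))
  rng <- apply(reference, 2, range, na.rm = TRUE)
  spec <- list(classes = classes, vars = vars,
               mins = rng[1, ], maxs = rng[2, ], n_knots = n_knots)
  # enumerate features: name + owning variable
  nm <- character(0); of <- character(0)
  if ("L" %in% classes) { nm <- c(nm, paste0("L:", vars)); of <- c(of, vars) }
  if ("Q" %in% classes) { nm <- c(nm, paste0("Q:", vars)); of <- c(of, vars) }
  if ("H" %in% classes) {
    knots <- seq(0, 1, length.out = n_knots + 1)
    fwd <- knots[-length(knots)]   # forward hinge knots (exclude 1)
    rev_ <- knots[-1]              # reverse hinge knots (exclude 0)
    for (v in vars) {
      nm <- c(nm, sprintf("H+:%s@%.4f", v, fwd), sprintf("H-:%s@%.4f", v, rev_))
      of <- c(of, rep(v, length(fwd) + length(rev_)))
    }
    spec$fwd_knots <- fwd; spec$rev_knots <- rev_
  }
  if ("P" %in% classes && length(vars) >= 2) {
    pr <- utils::combn(vars, 2)
    nm <- c(nm, paste0("P:", pr[1, ], "*", pr[2, ]))
    of <- c(of, paste0(pr[1, ], "*", pr[2, ]))  # product owned by both vars
    spec$pairs <- pr
  }
  spec$feature_names <- nm
  spec$feature_var <- of
  structure(spec, class = "feature_spec")
}

# standardize raw predictor values to [0,1] by the stored ranges, clamped
standardize_values <- function(values, spec) {
  values <- as.matrix(values)[, spec$vars, drop = FALSE]
  z <- sweep(values, 2, spec$mins)
  span <- spec$maxs - spec$mins
  span[span == 0] <- 1   # constant predictor -> all-zero feature
  z <- sweep(z, 2, span, "/")
  pmin(pmax(z, 0), 1)
}

#' Expand predictor values into the model's feature matrix
#'
#' @param values Numeric matrix of raw predictor values (rows = samples,
#'   columns named as in the spec).
#' @param spec A `feature_spec`.
#' @return Numeric matrix, one column per feature, deterministic order.
#' @export
build_features <- function(values, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  z <- standardize_values(values, spec)
  out <- list()
  if ("L" %in% spec$classes) out$L <- z
  if ("Q" %in% spec$classes) out$Q <- z^2
  if ("H" %in% spec$classes) {
    hl <- lapply(spec$vars, function(v) {
      zv <- z[, v]
      fwd <- vapply(spec$fwd_knots,
                    function(k) pmax(0, zv - k) / (1 - k), numeric(length(zv)))
      rev_ <- vapply(spec$rev_knots,
                     function(k) pmax(0, k - zv) / k, numeric(length(zv)))
      cbind(matrix(fwd, nrow = length(zv)), matrix(rev_, nrow = length(zv)))
    })
    out$H <- do.call(cbind, hl)
  }
  if ("P" %in% spec$classes && !is.null(spec$pairs)) {
    out$P <- vapply(seq_len(ncol(spec$pairs)),
                    function(i) z[, spec$pairs[1, i]] * z[, spec$pairs[2, i]],
                    numeric(nrow(z)))
    out$P <- matrix(out$P, nrow = nrow(z))
  }
  m <- do.call(cbind, out)
  colnames(m) <- spec$feature_names
  m
}

# per-feature penalty scale: linear/quadratic/product 1/sqrt(m),
# hinge 2.5/sqrt(m), scaled by rm in the fit
penalty_weights <- function(spec, n_presence) {
  base <- ifelse(startsWith(spec$feature_names, "H"), 2.5, 1)
  base / sqrt(n_presence)
}

# log( mean(exp(s)) ) with max-shift
log_mean_exp <- function(s) {
  m <- max(s)
  m + log(mean(exp(s - m)))
}

# smooth (unpenalized) part of the maxent objective
maxent_gain <- function(lambda, fp, fb) {
  mean(fp %*% lambda) - log_mean_exp(as.vector(fb %*% lambda))
}

#' Fit an L1-penalized maximum-entropy distribution model
#'
#' Maximizes the penalized maxent log-likelihood
#' `mean_presence(lambda . f) - log(mean_background(exp(lambda . f)))
#'  - rm * sum_j beta_j |lambda_j|`
#' by proximal gradient ascent with backtracking line search.
#' Per-feature penalties `beta_j` are `1/sqrt(m)` for linear, quadratic and
#' product features and `2.5/sqrt(m)` for hinge features (m = number of
#' presences), following standard maxent defaults. There is no intercept:
#' the log-partition term absorbs it.
#'
#' @param presence Matrix/data frame of raw predictor values at presence
#'   locations (>= 2 rows).
#' @param background Matrix/data frame of raw predictor values at
#'   background locations (defines the feature scaling).
#' @param fc Feature-class string (subset of `"LQHP"`).
#' @param rm Regularization multiplier (> 0).
#' @param max_iter Iteration cap (default 500).
#' @param tol Convergence threshold on the max absolute weight change
#'   (default 1e-5).
#' @param n_knots Hinge knots per predictor.
#' @return A `maxent_model`: feature weights, spec, normalizer (log of the
#'   background mean of `exp(score)`), entropy of the fitted background
#'   distribution, and a `converged` flag (cap reached without convergence
#'   raises a warning, not an error).
#' @export
fit_maxent <- function(presence, background, fc = "LQH", rm = 1,
                       max_iter = 500, tol = 1e-5, n_knots = 20) {
  presence <- as.matrix(presence)
  background <- as.matrix(background)
  if (nrow(presence) < 2) stop("need at least two presences", call. = FALSE)
  if (!nrow(background)) stop("background is empty", call. = FALSE)
  if (any(!is.finite(presence)) || any(!is.finite(background))) {
    stop("non-finite predictor values", call. = FALSE)
  }
  spec <- feature_spec(background, fc = fc, n_knots = n_knots)
  fp <- build_features(presence, spec)
  fb <- build_features(background, spec)
  pen <- rm * penalty_weights(spec, nrow(fp))
  fbar <- colMeans(fp)

  lambda <- rep(0, ncol(fp))
  step <- 1
  obj <- function(l) maxent_gain(l, fp, fb) - sum(pen * abs(l))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.vector(fb %*% lambda)
    sm <- max(s)
    w <- exp(s - sm); w <- w / sum(w)
    grad <- fbar - as.vector(crossprod(fb, w))
    g0 <- maxent_gain(lambda, fp, fb)
    repeat {
      cand <- lambda + step * grad
      cand <- sign(cand) * pmax(0, abs(cand) - step * pen)  # soft-threshold
      delta <- cand - lambda
      g1 <- maxent_gain(cand, fp, fb)
      if (g1 >= g0 + sum(grad * delta) - sum(delta^2) / (2 * step) - 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    moved <- max(abs(cand - lambda))
    lambda <- cand
    step <- min(step * 1.25, 1e3)
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("fit_maxent: iteration cap reached before convergence")
  }
  names(lambda) <- spec$feature_names
  sb <- as.vector(fb %*% lambda)
  log_norm <- log_mean_exp(sb)           # raw = exp(score - log_norm)
  raw_b <- exp(sb - log_norm)
  p <- raw_b / sum(raw_b)
  entropy <- -sum(ifelse(p > 0, p * log(p), 0))
  structure(
    list(lambda = lambda, spec = spec, rm = rm, penalties = pen,
         log_norm = log_norm, entropy = entropy, n_background = nrow(fb),
         background = background, n_presence = nrow(fp),
         converged = converged, objective = obj(lambda)),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> FC=%s RM=%g, %d features (%d nonzero), %s\n",
              paste(x$spec$classes, collapse = ""), x$rm, length(x$lambda),
              sum(x$lambda != 0),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d presences vs %d background; entropy %.4f\n",
              x$n_presence, x$n_background, x$entropy))
  invisible(x)
}

#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(feature = names(x$lambda),
                 variable = x$spec$feature_var,
                 weight = unname(x$lambda),
                 penalty = unname(x$penalties))
}

#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(fc = paste(x$spec$classes, collapse = ""), rm = x$rm,
                 n_features = length(x$lambda),
                 n_nonzero = sum(x$lambda != 0),
                 n_presence = x$n_presence, n_background = x$n_background,
                 entropy = x$entropy, converged = x$converged,
                 objective = x$objective)
}

# score predictor values under the model on each output scale
predict_values <- function(model, values,
                           output = c("cloglog", "logistic", "raw"),
                           tau = 0.5) {
  output <- match.arg(output)
  f <- build_features(values, model$spec)
  raw <- exp(as.vector(f %*% model$lambda) - model$log_norm)
  switch(output,
    raw = raw,
    logistic = tau * raw / ((1 - tau) + tau * raw),
    cloglog = {
      dens <- raw / model$n_background  # background-mean-1 raw -> density
      1 - exp(-exp(model$entropy) * dens)
    })
}

#' Predict habitat suitability over a raster stack
#'
#' Output scales: `raw` is the normalized exponential score (background
#' mean 1); `logistic` is `tau*raw/((1-tau)+tau*raw)` with default
#' prevalence `tau = 0.5`; `cloglog` is `1 - exp(-exp(H) * raw/n)` with H
#' the entropy of the fitted background distribution (the standard maxent
#' scaling). Logistic and cloglog are rank-identical monotone transforms
#' of raw.
#'
#' @param model A `maxent_model`.
#' @param stack Predictor stack whose layer names cover the training
#'   predictors.
#' @param output `"cloglog"` (default), `"logistic"` or `"raw"`.
#' @param tau Prevalence for the logistic transform.
#' @return A `raster_grid` of suitability.
#' @export
predict_suitability <- function(model, stack,
                                output = c("cloglog", "logistic", "raw"),
                                tau = 0.5) {
  output <- match.arg(output)
  stack <- check_stack(stack)
  miss <- setdiff(model$spec$vars, names(stack))
  if (length(miss)) {
    stop("stack is missing training predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- stack_values(stack)[, model$spec$vars, drop = FALSE]
  ok <- stats::complete.cases(vals)
  pred <- rep(NA_real_, nrow(vals))
  pred[ok] <- predict_values(model, vals[ok, , drop = FALSE], output, tau)
  tmpl <- stack[[1]]
  m <- matrix(pred, nrow = nrow(tmpl$values), ncol = ncol(tmpl$values),
              byrow = TRUE)
  raster_grid(m, tmpl$xmin, tmpl$ymin, tmpl$cell_size, crs = tmpl$crs,
              name = paste0("suitability_", output))
}

#' Save / load a fitted maxent model as JSON
#'
#' @param model A `maxent_model`.
#' @param path JSON file path.
#' @export
write_maxent_model <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  payload <- list(
    lambda = as.list(model$lambda), rm = model$rm,
    classes = model$spec$classes, vars = model$spec$vars,
    mins = as.list(stats::setNames(model$spec$mins, model$spec$vars)),
    maxs = as.list(stats::setNames(model$spec$maxs, model$spec$vars)),
    n_knots = model$spec$n_knots, log_norm = model$log_norm,
    entropy = model$entropy, n_background = model$n_background,
    n_presence = model$n_presence, converged = model$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
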