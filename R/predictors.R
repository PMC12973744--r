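#' Draw the shared cell subsample used for predictor screening
#'
#' Cells with any missing layer value are removed first, then a seeded
#' uniform subsample of at most `size` cells is drawn without replacement.
#' VIF filtering and the pairwise correlation matrix are computed on the
#' same subsample so the two screens see identical data.
#'
#' @param stack Predictor stack (named list of co-registered `raster_grid`).
#' @param size Maximum number of cells (default 10,000).
#' @param seed Integer seed.
#' @return Integer vector of row indices into the cell-value matrix.
#' @export
screening_subsample <- function(stack, size = 10000, seed = 1L) {
  vals <- stack_values(stack)
  complete <- which(stats::complete.cases(vals))
  if (!length(complete)) stop("no cells without missing values", call. = FALSE)
  if (length(complete) <= size) return(complete)
  withr::with_seed(as.integer(seed), sample(complete, size))
}

vif_one <- function(j, dat) {
  others <- dat[, -j, drop = FALSE]
  fit <- stats::lm(dat[, j] ~ ., data = as.data.frame(others))
  # summary() warns on an exactly collinear (perfect) fit; that case is
  # handled explicitly below as VIF = Inf
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' Iterative variance-inflation-factor filtering of a predictor stack
#'
#' Multicollinearity screen: each layer is regressed (OLS) on all other
#' retained layers over a seeded subsample of complete cells, giving
#' `VIF = 1/(1 - R^2)`. While the largest VIF exceeds the threshold, that
#' layer is dropped and all VIFs recomputed (worst-first removal). Exactly
#' collinear layers have infinite VIF and are dropped first.
#'
#' @param stack Predictor stack with at least two layers.
#' @param threshold VIF cutoff (default 5).
#' @param subsample_size Cells used (default 10,000).
#' @param seed Integer seed for the subsample.
#' @return A `vif_report`: list with `kept`, `dropped` (tibble of variable
#'   and the iteration it was removed), `history` (per-iteration VIFs),
#'   `threshold`, `subsample_size`, `seed`. `tidy()` returns the history.
#' @export
vif_filter <- function(stack, threshold = 5, subsample_size = 10000,
                       seed = 1L) {
  stack <- check_stack(stack)
  if (length(stack) < 2L) stop("need at least two layers", call. = FALSE)
  idx <- screening_subsample(stack, subsample_size, seed)
  vals <- stack_values(stack)[idx, , drop = FALSE]
  vars <- colnames(vals)
  retained <- vars
  history <- list()
  dropped <- tibble::tibble(variable = character(0), iteration = integer(0),
                            vif = numeric(0))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dat <- vals[, retained, drop = FALSE]
    if (length(retained) == 1L) {
      vifs <- stats::setNames(1, retained)
    } else {
      vifs <- vapply(seq_along(retained), vif_one, numeric(1), dat = dat)
      names(vifs) <- retained
    }
    history[[iter]] <- tibble::tibble(iteration = iter,
                                      variable = names(vifs),
                                      vif = unname(vifs))
    worst <- which.max(vifs)
    if (length(retained) > 1L && vifs[worst] > threshold) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        variable = names(vifs)[worst], iteration = iter,
        vif = unname(vifs[worst])))
      retained <- setdiff(retained, names(vifs)[worst])
    } else break
  }
  structure(
    list(kept = retained, dropped = dropped,
         history = dplyr::bind_rows(history),
         threshold = threshold, subsample_size = subsample_size,
         seed = as.integer(seed), subsample = idx),
    class = "vif_report"
  )
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> threshold %g, %d kept, %d dropped\n",
              x$threshold, length(x$kept), nrow(x$dropped)))
  final <- x$history[x$history$iteration == max(x$history$iteration), ]
  cat("  kept:", paste(sprintf("%s (%.2f)", final$variable, final$vif),
                       collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped:", paste(sprintf("%s (it %d, VIF %.2f)", x$dropped$variable,
                                    x$dropped$iteration, x$dropped$vif),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.vif_report <- function(x, ...) {
  dplyr::mutate(x$history,
                dropped = paste(.data$variable, .data$iteration) %in%
                  paste(x$dropped$variable, x$dropped$iteration))
}

#' @export
glance.vif_report <- function(x, ...) {
  tibble::tibble(n_input = length(x$kept) + nrow(x$dropped),
                 n_kept = length(x$kept), n_dropped = nrow(x$dropped),
                 threshold = x$threshold, subsample_size = x$subsample_size,
                 seed = x$seed)
}

#' Pairwise Pearson correlation among predictor layers
#'
#' Computed over the same seeded subsample of complete cells used by
#' [vif_filter()]. Zero-variance layers yield `NA` correlations with a
#' warning.
#'
#' @param stack Predictor stack (>= 2 layers).
#' @param subsample Optional cell indices (from [screening_subsample()]);
#'   drawn fresh with `seed` if omitted.
#' @param subsample_size,seed Passed to [screening_subsample()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_predictor_correlation <- function(stack, subsample = NULL,
                                           subsample_size = 10000,
                                           seed = 1L) {
  stack <- check_stack(stack)
  if (length(stack) < 2L) stop("need at least two layers", call. = FALSE)
  if (is.null(subsample)) {
    subsample <- screening_subsample(stack, subsample_size, seed)
  }
  vals <- stack_values(stack)[subsample, , drop = FALSE]
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance layer(s): ",
            paste(colnames(vals)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(m <- stats::cor(vals, method = "pearson"))
  diag(m) <- 1
  m
}

#' Gaussian kernel-density sampling-bias layer
#'
#' Weighted isotropic Gaussian KDE of occurrence records evaluated at cell
#' centers, each record weighted by its `count` (individuals per
#' observation), then min-max rescaled to [0, 1]; cells with zero density
#' get exactly 0. The result is the bias layer used to steer background
#' sampling toward surveyed areas.
#'
#' @param occ An `occurrence_set` (>= 1 record).
#' @param grid Target `raster_grid` (geometry only; values ignored).
#' @param sigma Kernel bandwidth in meters (default 3000, i.e. 3 km).
#' @param weights Per-record weights; default the `count` column. Must not
#'   be all zero.
#' @return A `raster_grid` with values in [0, 1].
#' @export
kde_bias_layer <- function(occ, grid, sigma = 3000, weights = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "raster_grid"),
            sigma > 0)
  if (!nrow(occ)) stop("need at least one occurrence point", call. = FALSE)
  w <- if (is.null(weights)) as.numeric(occ$count) else as.numeric(weights)
  stopifnot(length(w) == nrow(occ), all(w >= 0))
  if (all(w == 0)) stop("all weights are zero", call. = FALSE)
  xy <- raster_xy(grid)
  inv2s2 <- 1 / (2 * sigma^2)
  # sum_k w_k * exp(-d^2 / 2 sigma^2) / (2 pi sigma^2), cells x points
  dens <- numeric(nrow(xy))
  for (k in seq_len(nrow(occ))) {
    if (w[k] == 0) next
    d2 <- (xy$x - occ$x[k])^2 + (xy$y - occ$y[k])^2
    dens <- dens + w[k] * exp(-d2 * inv2s2)
  }
  dens <- dens / (2 * pi * sigma^2)
  rng <- range(dens)
  scaled <- if (rng[2] > rng[1]) (dens - rng[1]) / (rng[2] - rng[1])
            else rep(1, length(dens))
  scaled[dens == 0] <- 0
  m <- matrix(scaled, nrow = nrow(grid$values), ncol = ncol(grid$values),
              byrow = TRUE)
  raster_grid(m, grid$xmin, grid$ymin, grid$cell_size, crs = grid$crs,
              name = "bias")
}

#' Extract iso-density contour polylines from a bias layer
#'
#' Optional diagnostic export: marching contour lines of the normalized
#' density surface at user-supplied levels. Feeds nothing downstream.
#'
#' @param bias A `raster_grid` (typically from [kde_bias_layer()]).
#' @param levels Numeric contour levels in (0, 1).
#' @return Tibble with `level`, `line`, `x`, `y` vertices.
#' @export
bias_contours <- function(bias, levels = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(bias, "raster_grid"))
  nr <- nrow(bias$values); nc <- ncol(bias$values)
  ymax <- bias$ymin + nr * bias$cell_size
  xs <- bias$xmin + (seq_len(nc) - 0.5) * bias$cell_size
  ys <- ymax - (seq_len(nr) - 0.5) * bias$cell_size
  # contourLines wants increasing coordinates: flip rows, transpose to x,y
  z <- t(bias$values[nr:1, , drop = FALSE])
  cl <- grDevices::contourLines(x = xs, y = rev(ys), z = z, levels = levels)
  if (!length(cl)) {
    return(tibble::tibble(level = numeric(0), line = integer(0),
                          x = numeric(0), y = numeric(0)))
  }
  purrr::imap_dfr(cl, function(li, i) {
    tibble::tibble(level = li$level, line = i, x = li$x, y = li$y)
  })
}
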