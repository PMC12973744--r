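#' Pairwise Euclidean distance matrix of point coordinates
#'
#' @param points Data frame/tibble with `x`, `y` and optionally `id`
#'   (defaults to row number); >= 2 points, unique ids.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
euclidean_distance_matrix <- function(points) {
  stopifnot(nrow(points) >= 2, all(c("x", "y") %in% names(points)))
  ids <- if ("id" %in% names(points)) as.character(points$id)
         else as.character(seq_len(nrow(points)))
  if (anyDuplicated(ids)) stop("duplicate point ids", call. = FALSE)
  m <- as.matrix(stats::dist(cbind(points$x, points$y)))
  dimnames(m) <- list(ids, ids)
  m
}

#' Subsample two species' point sets to a common size
#'
#' The Mantel test needs distance matrices of equal dimension; when two
#' species have unequal record counts the larger set is subsampled
#' (seeded, without replacement) to the size of the smaller. Row order of
#' the retained points is preserved.
#'
#' @param occA,occB Occurrence tibbles (or any data frame with `x`, `y`).
#' @param seed Integer seed.
#' @return List of two tibbles of equal size (`a`, `b`).
#' @export
pair_species_points <- function(occA, occB, seed = 1L) {
  stopifnot(nrow(occA) > 0, nrow(occB) > 0)
  n <- min(nrow(occA), nrow(occB))
  sub <- function(df) {
    if (nrow(df) == n) return(tibble::as_tibble(df)[, c("x", "y")])
    keep <- withr::with_seed(as.integer(seed),
                             sort(sample.int(nrow(df), n)))
    tibble::as_tibble(df)[keep, c("x", "y")]
  }
  list(a = sub(occA), b = sub(occB))
}

mantel_r <- function(mA, mB) {
  lt <- lower.tri(mA)
  stats::cor(mA[lt], mB[lt])
}

#' Mantel permutation test of distance-matrix correlation
#'
#' The statistic is the Pearson correlation of the strictly-lower-triangle
#' entries. The null distribution is generated by jointly permuting the
#' rows and columns of the second matrix; the p-value is one-tailed upper
#' (spatial association), `(exceedances + 1) / (n_perm + 1)`, so p can
#' never be 0 and never drops below `1/(n_perm + 1)`. Upper null quantiles
#' at 90/95/97.5/99% are reported alongside. With
#' `permutations = "exact"` all `n!` relabelings are enumerated (n <= 7)
#' and the p-value is exact.
#'
#' @param mA,mB Square distance matrices of equal dimension (>= 3).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param permutations `"random"` or `"exact"`.
#' @return A `mantel_result`: `r`, `p`, `n_perm`, `null_quantiles`, `seed`.
#' @export
mantel_test <- function(mA, mB, n_perm = 999, seed = 1L,
                        permutations = c("random", "exact")) {
  permutations <- match.arg(permutations)
  stopifnot(is.matrix(mA), is.matrix(mB), all(dim(mA) == dim(mB)),
            nrow(mA) >= 3)
  lt <- lower.tri(mA)
  if (stats::sd(mA[lt]) == 0 || stats::sd(mB[lt]) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  r_obs <- mantel_r(mA, mB)
  n <- nrow(mA)
  if (permutations == "exact") {
    if (n > 7) stop("exact enumeration limited to n <= 7", call. = FALSE)
    perms <- all_permutations(n)
    null_r <- vapply(perms, function(p) mantel_r(mA, mB[p, p]), numeric(1))
    # identity permutation is part of the enumeration: p = Pr(null >= obs)
    p_val <- mean(null_r >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    null_r <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        p <- sample.int(n)
        mantel_r(mA, mB[p, p])
      }, numeric(1))
    })
    p_val <- (sum(null_r >= r_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(
    list(r = r_obs, p = p_val, n_perm = n_used,
         null_quantiles = stats::quantile(null_r,
                                          c(0.90, 0.95, 0.975, 0.99)),
         null_r = null_r, seed = as.integer(seed),
         permutations = permutations),
    class = "mantel_result"
  )
}

# all permutations of 1..n as a list: insert n at every position of each
# permutation of 1..(n-1); n! entries, n small
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos)
    }
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$permutations, x$n_perm))
  q <- x$null_quantiles
  cat(sprintf("  null quantiles: 90%% %.4f | 95%% %.4f | 97.5%% %.4f | 99%% %.4f\n",
              q[1], q[2], q[3], q[4]))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r = x$r, p = x$p, n_perm = x$n_perm,
                 null_q90 = unname(x$null_quantiles[1]),
                 null_q95 = unname(x$null_quantiles[2]),
                 null_q975 = unname(x$null_quantiles[3]),
                 null_q99 = unname(x$null_quantiles[4]))
}

#' @export
glance.mantel_result <- tidy.mantel_result

#' Mantel association between two species' occurrence sets
#'
#' End-to-end wrapper: subsample to a common size with
#' [pair_species_points()], build Euclidean distance matrices, run the
#' Mantel test. Because the subsample of the larger set is itself random,
#' the procedure is repeated over `n_draws` seeded subsample draws and the
#' median r and p are reported with their spread; `n_draws = 1` mimics a
#' single-draw analysis.
#'
#' @param occA,occB Occurrence tibbles (single species each).
#' @param n_perm Mantel permutations per draw (default 999).
#' @param n_draws Subsample draws (default 100).
#' @param seed Integer seed.
#' @return Tibble with median/IQR of r and p over draws, plus the
#'   `mantel_result` of the first draw in attribute `"first_draw"`.
#' @export
mantel_association <- function(occA, occB, n_perm = 999, n_draws = 100,
                               seed = 1L) {
  draws <- purrr::map_dfr(seq_len(n_draws), function(i) {
    s <- as.integer(seed) + i - 1L
    pr <- pair_species_points(occA, occB, seed = s)
    mt <- mantel_test(euclidean_distance_matrix(pr$a),
                      euclidean_distance_matrix(pr$b),
                      n_perm = n_perm, seed = s)
    tibble::tibble(draw = i, r = mt$r, p = mt$p)
  })
  out <- tibble::tibble(
    n_draws = n_draws,
    r_median = stats::median(draws$r), r_iqr = stats::IQR(draws$r),
    p_median = stats::median(draws$p), p_iqr = stats::IQR(draws$p)
  )
  attr(out, "draws") <- draws
  out
}

#' Schoener's D niche overlap between two suitability maps
#'
#' Both rasters are normalized to sum 1 over the shared valid cells
#' (turning them into spatial probability distributions p and q);
#' `D = 1 - 0.5 * sum |p_i - q_i|`, from 0 (disjoint) to 1 (identical).
#' Symmetric and invariant to positive rescaling of either raster.
#'
#' @param suitA,suitB Aligned nonnegative `raster_grid`s with at least one
#'   positive cell each.
#' @return Schoener's D in [0, 1].
#' @export
schoener_overlap <- function(suitA, suitB) {
  stopifnot(inherits(suitA, "raster_grid"), inherits(suitB, "raster_grid"))
  if (!same_geometry(suitA, suitB)) {
    stop("rasters are not aligned; run align_rasters() first", call. = FALSE)
  }
  a <- raster_values(suitA); b <- raster_values(suitB)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (any(a < 0) || any(b < 0)) {
    stop("suitability values must be nonnegative", call. = FALSE)
  }
  if (sum(a) == 0 || sum(b) == 0) {
    stop("all-zero raster: overlap undefined", call. = FALSE)
  }
  p <- a / sum(a); q <- b / sum(b)
  1 - 0.5 * sum(abs(p - q))
}

# 4x4 equal-area spatial blocks with proportional allocation
stratified_rows <- function(xy, max_n, seed, nx = 4, ny = 4) {
  n <- nrow(xy)
  if (n <= max_n) return(seq_len(n))
  bx <- pmin(floor((xy$x - min(xy$x)) / (diff(range(xy$x)) + 1e-9) * nx), nx - 1)
  by <- pmin(floor((xy$y - min(xy$y)) / (diff(range(xy$y)) + 1e-9) * ny), ny - 1)
  stratum <- bx * ny + by
  withr::with_seed(as.integer(seed), {
    take <- unlist(lapply(split(seq_len(n), stratum), function(idx) {
      k <- max(1L, round(length(idx) / n * max_n))
      sample(idx, min(k, length(idx)))
    }))
  })
  sort(take)
}

#' Pairwise correlation suite over aligned suitability rasters
#'
#' Cells become observation rows (missing values excluded). Pearson
#' correlations with two-sided tests are computed on all valid rows.
#' The Spearman branch first drops rows where every layer is zero (to
#' reduce the influence of the shared unsuitable background), then takes a
#' stratified seeded subsample of at most `max_n` rows (4 x 4 equal-area
#' spatial blocks, proportional allocation). Each family of pairwise
#' p-values is Benjamini-Hochberg adjusted.
#'
#' @param stack Named list of aligned suitability `raster_grid`s (>= 2).
#' @param max_n Subsample cap for the Spearman branch (default 5,000).
#' @param seed Integer seed for the subsample.
#' @param drop_all_zero Drop all-zero rows in the Spearman branch (default
#'   `TRUE`); set `pearson_filter = TRUE` to extend the filter to Pearson.
#' @param pearson_filter Apply the same filter + subsample to Pearson.
#' @return An `overlap_report` tibble: one row per layer pair with
#'   `pearson_r`, `pearson_p`, `pearson_p_adj`, `spearman_rho`,
#'   `spearman_p`, `spearman_p_adj`, `n_pearson`, `n_spearman`.
#' @export
correlation_suite <- function(stack, max_n = 5000, seed = 1L,
                              drop_all_zero = TRUE, pearson_filter = FALSE) {
  stack <- check_stack(stack)
  if (length(stack) < 2L) stop("need at least two layers", call. = FALSE)
  vals <- stack_values(stack)
  xy <- raster_xy(stack[[1]])
  ok <- stats::complete.cases(vals)
  vals <- vals[ok, , drop = FALSE]
  xy <- xy[ok, ]
  # Spearman branch: optional all-zero-row filter, then capped subsample
  sp_keep <- if (drop_all_zero) rowSums(vals != 0) > 0 else rep(TRUE, nrow(vals))
  sp_rows <- which(sp_keep)[stratified_rows(xy[sp_keep, ], max_n, seed)]
  pe_rows <- if (pearson_filter) sp_rows else seq_len(nrow(vals))
  pairs <- utils::combn(colnames(vals), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    pe <- cor_or_na(vals[pe_rows, a], vals[pe_rows, b], "pearson")
    sp <- cor_or_na(vals[sp_rows, a], vals[sp_rows, b], "spearman")
    tibble::tibble(species_a = a, species_b = b,
                   pearson_r = pe$estimate, pearson_p = pe$p,
                   spearman_rho = sp$estimate, spearman_p = sp$p,
                   n_pearson = length(pe_rows), n_spearman = length(sp_rows))
  })
  res$pearson_p_adj <- stats::p.adjust(res$pearson_p, method = "BH")
  res$spearman_p_adj <- stats::p.adjust(res$spearman_p, method = "BH")
  class(res) <- c("overlap_report", class(res))
  res
}

cor_or_na <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance layer in correlation pair; reported as NA")
    return(list(estimate = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value)
}

#' Full overlap report between a focal species and others
#'
#' Convenience wrapper combining Schoener's D and the correlation suite
#' for every pair in a suitability stack.
#'
#' @inheritParams correlation_suite
#' @return Tibble: pair, `schoener_d`, correlation columns.
#' @export
overlap_report <- function(stack, max_n = 5000, seed = 1L,
                           drop_all_zero = TRUE) {
  stack <- check_stack(stack)
  cs <- correlation_suite(stack, max_n = max_n, seed = seed,
                          drop_all_zero = drop_all_zero)
  cs$schoener_d <- purrr::map2_dbl(cs$species_a, cs$species_b,
                                   ~schoener_overlap(stack[[.x]], stack[[.y]]))
  dplyr::relocate(cs, "schoener_d", .after = "species_b")
}
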