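test_that("Euclidean distance matrices are exact and symmetric", {
  m <- euclidean_distance_matrix(tibble::tibble(x = c(0, 3), y = c(0, 4)))
  expect_equal(m[1, 2], 5)   # 3-4-5 triangle
  expect_equal(diag(m), c("1" = 0, "2" = 0))
  m2 <- euclidean_distance_matrix(tibble::tibble(x = c(1, 1, 7),
                                                 y = c(2, 2, -3)))
  expect_equal(m2[1, 2], 0)   # identical points
  expect_equal(m2, t(m2))
  expect_error(euclidean_distance_matrix(
    tibble::tibble(id = c("a", "a"), x = 1:2, y = 1:2)), "duplicate")
})

test_that("species pairing subsamples the larger set reproducibly", {
  a <- tibble::tibble(x = runif(126), y = runif(126))
  b <- tibble::tibble(x = runif(280), y = runif(280))
  pr <- pair_species_points(a, b, seed = 5)
  expect_equal(nrow(pr$a), 126)
  expect_equal(nrow(pr$b), 126)
  expect_identical(pr, pair_species_points(a, b, seed = 5))
  same <- pair_species_points(a, a, seed = 5)
  expect_equal(same$a, same$b)
})

test_that("Mantel: identical matrices, p-value floor, determinism", {
  set.seed(31)
  pts <- tibble::tibble(x = runif(30), y = runif(30))
  m <- euclidean_distance_matrix(pts)
  mt <- mantel_test(m, m, n_perm = 999, seed = 1)
  expect_equal(mt$r, 1)
  expect_gte(mt$p, 1 / 1000)   # (exceedances+1)/(n_perm+1) floor
  expect_identical(mantel_test(m, m, n_perm = 99, seed = 3),
                   mantel_test(m, m, n_perm = 99, seed = 3))
})

test_that("Mantel constant-matrix input is an error", {
  const <- matrix(2, 4, 4); diag(const) <- 0
  other <- euclidean_distance_matrix(tibble::tibble(x = runif(4),
                                                    y = runif(4)))
  expect_error(mantel_test(const, other), "constant")
})

test_that("exact Mantel enumeration equals the brute-force oracle", {
  set.seed(32)
  for (n in 4:5) {
    a <- euclidean_distance_matrix(tibble::tibble(x = runif(n), y = runif(n)))
    b <- euclidean_distance_matrix(tibble::tibble(x = runif(n), y = runif(n)))
    got <- mantel_test(a, b, permutations = "exact")
    # independent oracle: loop every relabeling, count r_null >= r_obs
    lt <- lower.tri(a)
    r_obs <- cor(a[lt], b[lt])
    perms <- do.call(rbind, combinat_perms(n))
    r_null <- apply(perms, 1, function(p) cor(a[lt], b[p, p][lt]))
    expect_equal(got$n_perm, factorial(n))
    expect_equal(got$p, mean(r_null >= r_obs - 1e-12))
    expect_equal(got$r, r_obs)
  }
})

test_that("Mantel null: independent point sets rarely flag association", {
  reps <- 50
  flags <- vapply(seq_len(reps), function(i) {
    set.seed(1000 + i)
    a <- euclidean_distance_matrix(tibble::tibble(x = runif(100),
                                                  y = runif(100)))
    b <- euclidean_distance_matrix(tibble::tibble(x = runif(100),
                                                  y = runif(100)))
    mt <- mantel_test(a, b, n_perm = 199, seed = i)
    abs(mt$r) < 0.1 && mt$p > 0.05
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})

test_that("Mantel agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(33)
  pts <- tibble::tibble(x = runif(40), y = runif(40))
  warped <- tibble::tibble(x = pts$x + rnorm(40, 0, 0.1), y = pts$y)
  a <- euclidean_distance_matrix(pts)
  b <- euclidean_distance_matrix(warped)
  ours <- mantel_test(a, b, n_perm = 999, seed = 4)
  ref <- vegan::mantel(stats::as.dist(a), stats::as.dist(b),
                       permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("mantel_association reports median over subsample draws", {
  set.seed(34)
  # matched same-size sets (jittered copy): strong spatial congruence
  a <- tibble::tibble(x = runif(40), y = runif(40))
  b <- tibble::tibble(x = a$x + rnorm(40, 0, 0.02),
                      y = a$y + rnorm(40, 0, 0.02))
  res <- mantel_association(a, b, n_perm = 99, n_draws = 3, seed = 2)
  expect_equal(res$n_draws, 3)
  expect_gt(res$r_median, 0.5)
  expect_lt(res$p_median, 0.05)
  expect_equal(nrow(attr(res, "draws")), 3)

  # unequal sizes: each draw subsamples the larger set; results stay valid
  # and the summary is reproducible under the same seed
  b2 <- dplyr::bind_rows(b, tibble::tibble(x = runif(20), y = runif(20)))
  r1 <- mantel_association(a, b2, n_perm = 99, n_draws = 5, seed = 3)
  r2 <- mantel_association(a, b2, n_perm = 99, n_draws = 5, seed = 3)
  expect_identical(r1, r2)
  dr <- attr(r1, "draws")
  expect_true(all(dr$r >= -1 & dr$r <= 1))
  expect_true(all(dr$p > 0 & dr$p <= 1))
})

test_that("Schoener's D: identity, disjointness, symmetry, scaling", {
  a <- grid_from(matrix(runif(100), 10, 10))
  expect_equal(schoener_overlap(a, a), 1)
  left <- grid_from(cbind(matrix(1, 10, 5), matrix(0, 10, 5)))
  right <- grid_from(cbind(matrix(0, 10, 5), matrix(1, 10, 5)))
  expect_equal(schoener_overlap(left, right), 0)
  b <- grid_from(matrix(runif(100), 10, 10))
  expect_equal(schoener_overlap(a, b), schoener_overlap(b, a))
  b2 <- b; b2$values <- b$values * 37.5
  expect_equal(schoener_overlap(a, b2), schoener_overlap(a, b),
               tolerance = 1e-12)
  # hand-computed two-cell example: p=(.5,.5), q=(1,0) -> D = 0.5
  p <- grid_from(matrix(c(0.5, 0.5), 1, 2))
  q <- grid_from(matrix(c(1, 0), 1, 2))
  expect_equal(schoener_overlap(p, q), 0.5)
  zero <- grid_from(matrix(0, 10, 10))
  expect_error(schoener_overlap(a, zero), "all-zero")
  expect_error(schoener_overlap(a, grid_from(matrix(1, 5, 5))), "aligned")
})

test_that("correlation suite: rank invariance, filters, BH adjustment", {
  set.seed(35)
  v <- runif(400)
  st <- stack_from(a = v, mono = exp(3 * v), c = runif(400),
                   nr = 20, nc = 20)
  cs <- correlation_suite(st, max_n = 5000, seed = 1)
  row_am <- cs[cs$species_a == "a" & cs$species_b == "mono", ]
  expect_equal(row_am$spearman_rho, 1)    # monotone transform: rank-identical
  expect_lt(row_am$pearson_r, 1)
  expect_gt(row_am$pearson_r, 0.8)
  # BH: adjusted >= raw, monotone in raw ordering, bounded by 1
  expect_true(all(cs$pearson_p_adj >= cs$pearson_p, na.rm = TRUE))
  o <- order(cs$pearson_p)
  expect_true(!is.unsorted(cs$pearson_p_adj[o]))
  expect_true(all(cs$pearson_p_adj <= 1, na.rm = TRUE))
  expect_equal(cs$pearson_p_adj, p.adjust(cs$pearson_p, "BH"))

  # identical layers correlate exactly
  st2 <- stack_from(a = v, b = v, nr = 20, nc = 20)
  cs2 <- correlation_suite(st2, seed = 1)
  expect_equal(cs2$pearson_r, 1)
  expect_equal(cs2$spearman_rho, 1)

  # all-zero-row filter applies to the Spearman branch only
  z <- c(rep(0, 200), runif(200))
  st3 <- stack_from(a = z, b = c(rep(0, 200), runif(200)), nr = 20, nc = 20)
  cs3 <- correlation_suite(st3, seed = 1, drop_all_zero = TRUE)
  expect_equal(cs3$n_spearman, 200)
  expect_equal(cs3$n_pearson, 400)

  # the subsample cap and seed make the Spearman branch reproducible
  big <- stack_from(a = runif(10000), b = runif(10000), nr = 100, nc = 100)
  c1 <- correlation_suite(big, max_n = 5000, seed = 9)
  c2 <- correlation_suite(big, max_n = 5000, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$n_spearman, 5000)

  stz <- stack_from(a = v, const = rep(1, 400), nr = 20, nc = 20)
  w <- testthat::capture_warnings(csz <- correlation_suite(stz, seed = 1))
  expect_true(any(grepl("zero-variance", w)))
  expect_true(is.na(csz$pearson_r))
  expect_true(is.na(csz$spearman_rho))
})

test_that("overlap report combines Schoener's D with the correlation suite", {
  st <- test_stack(seed = 36, n_layers = 2)
  # use the two landscape layers as stand-in suitability surfaces (shifted
  # to be nonnegative)
  s1 <- st$env1; s1$values <- s1$values - min(s1$values)
  s2 <- st$env2; s2$values <- s2$values - min(s2$values)
  rep_ <- overlap_report(list(wolf = s1, roe = s2), seed = 1)
  expect_equal(nrow(rep_), 1)
  expect_true(rep_$schoener_d >= 0 && rep_$schoener_d <= 1)
  expect_true(all(c("pearson_r", "spearman_rho", "pearson_p_adj",
                    "spearman_p_adj") %in% names(rep_)))
})

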