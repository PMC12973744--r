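# shared fixtures: everything generated in code, nothing on disk

# raster from a matrix (row 1 = north), 100 m cells at the origin
grid_from <- function(m, cell_size = 100, xmin = 0, ymin = 0,
                      name = "layer") {
  raster_grid(m, xmin, ymin, cell_size, name = name)
}

# small co-registered stack built directly from value vectors (one row
# per layer, each length nr*nc in row-major order)
stack_from <- function(..., nr, nc, cell_size = 100) {
  vs <- list(...)
  nm <- names(vs)
  if (is.null(nm)) nm <- paste0("v", seq_along(vs))
  st <- lapply(seq_along(vs), function(i) {
    grid_from(matrix(vs[[i]], nr, nc, byrow = TRUE), cell_size,
              name = nm[i])
  })
  names(st) <- nm
  st
}

# default small landscape used across tests (40 x 50 cells, 100 m)
test_extent <- c(0, 0, 5000, 4000)

test_stack <- function(seed = 42, n_layers = 3) {
  generate_predictor_stack(seed = seed, extent = test_extent,
                           cell_size = 100, n_layers = n_layers)
}

test_truth <- function(seed = 7, stack = NULL, ...) {
  scenario_truth(seed = seed, extent = test_extent, cell_size = 100,
                 species_coefficients = list(
                   wolf = c(1.5, 0, -0.3),
                   roe_deer = c(1.0, 0.5, 0),
                   red_deer = c(0.8, -0.5, 0),
                   wild_boar = c(0.2, 0.2, 0.1)),
                 ...)
}

# write an occurrence CSV from a data frame of character columns
write_occ_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force reference AUC by exhaustive pair counting (ties = 1/2)
auc_pairs <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# independent oracle for the exact Mantel test: enumerate all permutations
# (recursive insertion), written without touching the package internals
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, pos)
  }
  out
}
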