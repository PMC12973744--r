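#' Ground truth for a synthetic predator-prey scenario
#'
#' Bundles everything the generators need, and everything the recovery tests
#' check against: the true animal density, the movement and detection-zone
#' parameters of the random encounter model, and the per-species linear
#' coefficients that tie occurrence intensity to the predictor stack.
#'
#' @param seed Integer seed; every generator is a pure function of it.
#' @param true_density True density, individuals per km^2 (>= 0).
#' @param true_speed Daily movement speed, km/day (> 0).
#' @param true_radius Camera detection-zone radius, km (> 0).
#' @param true_angle Detection-zone angle, radians (in (0, 2*pi]).
#' @param species_coefficients Named list: species -> numeric vector of
#'   linear-predictor coefficients, one per stack layer (recycled names are
#'   matched by position to layers).
#' @param extent Numeric `c(xmin, ymin, xmax, ymax)` in meters.
#' @param cell_size Cell size in meters (> 0).
#' @return A `scenario_truth` object.
#' @export
scenario_truth <- function(seed = 1L,
                           true_density = 1.2,
                           true_speed = 16,
                           true_radius = 0.020,
                           true_angle = 0.77,
                           species_coefficients = list(),
                           extent = c(0, 0, 10000, 10000),
                           cell_size = 100) {
  stopifnot(true_density >= 0, true_speed > 0, true_radius > 0,
            true_angle > 0, true_angle <= 2 * pi, cell_size > 0)
  if (length(extent) != 4L || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("`extent` must be c(xmin, ymin, xmax, ymax) with positive area",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), true_density = true_density,
         true_speed = true_speed, true_radius = true_radius,
         true_angle = true_angle,
         species_coefficients = species_coefficients,
         extent = as.numeric(extent), cell_size = cell_size),
    class = "scenario_truth"
  )
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf(
    "<scenario_truth> D=%g ind/km^2, v=%g km/day, r=%g km, theta=%g rad, seed=%d\n",
    x$true_density, x$true_speed, x$true_radius, x$true_angle, x$seed))
  cat(sprintf("  extent %g x %g km, cell %g m, %d species\n",
              (x$extent[3] - x$extent[1]) / 1000,
              (x$extent[4] - x$extent[2]) / 1000,
              x$cell_size, length(x$species_coefficients)))
  invisible(x)
}

# isotropic Gaussian blur of a matrix via separable convolution,
# reflecting at edges; bandwidth in cells
gauss_blur <- function(m, bw) {
  half <- max(1L, ceiling(3 * bw))
  k <- stats::dnorm(seq(-half, half), sd = bw)
  k <- k / sum(k)
  pad_reflect <- function(v, h) c(rev(v[seq_len(h)]), v, rev(v[(length(v) - h + 1):length(v)]))
  conv1 <- function(v) {
    p <- pad_reflect(v, half)
    stats::filter(p, k, sides = 2)[(half + 1):(half + length(v))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Generate a co-registered stack of synthetic environmental predictors
#'
#' Emulates the kind of predictor set used for habitat modelling in a
#' Mediterranean protected area: smooth continuous fields (elevation-like
#' Gaussian random fields, smoothing bandwidth 5 cells) plus
#' distance-to-class rasters obtained by thresholding the first field into a
#' categorical map (habitat patches) and taking the Euclidean distance
#' transform.
#'
#' @param seed Integer seed.
#' @param extent `c(xmin, ymin, xmax, ymax)` meters; must have positive area.
#' @param cell_size Cell size, meters.
#' @param n_layers Number of layers (>= 2); layers alternate smooth fields
#'   and distance layers, starting with two smooth fields.
#' @param bandwidth Gaussian smoothing bandwidth in cells.
#' @return Named list of `raster_grid`s (`env1`, `env2`, ..., `dist1`, ...).
#' @export
generate_predictor_stack <- function(seed, extent, cell_size, n_layers = 4,
                                     bandwidth = 5) {
  stopifnot(n_layers >= 2)
  if (length(extent) != 4L || extent[3] <= extent[1] || extent[4] <= extent[2]) {
    stop("degenerate extent: zero area", call. = FALSE)
  }
  nc <- round((extent[3] - extent[1]) / cell_size)
  nr <- round((extent[4] - extent[2]) / cell_size)
  if (nr < 20 || nc < 20) {
    stop("grid must be at least 20 x 20 cells", call. = FALSE)
  }
  n_smooth <- ceiling(n_layers / 2) + ifelse(n_layers == 2, 1, 0)
  n_smooth <- min(n_smooth, n_layers)
  n_dist <- n_layers - n_smooth
  withr::with_seed(as.integer(seed), {
    fields <- lapply(seq_len(n_smooth), function(i) {
      f <- gauss_blur(matrix(stats::rnorm(nr * nc), nr, nc), bandwidth)
      (f - mean(f)) / stats::sd(f)   # unit-variance landscape field
    })
    stack <- lapply(seq_along(fields), function(i) {
      raster_grid(fields[[i]], extent[1], extent[2], cell_size,
                  name = paste0("env", i))
    })
    names(stack) <- paste0("env", seq_len(n_smooth))
    if (n_dist > 0) {
      # threshold the first field at descending quantiles -> habitat classes
      qs <- stats::quantile(fields[[1]], probs = seq(0.7, 0.9, length.out = n_dist))
      for (j in seq_len(n_dist)) {
        cls <- raster_grid((fields[[1]] >= qs[j]) * 1,
                           extent[1], extent[2], cell_size, name = "class")
        d <- suppressWarnings(distance_to_class(cls, 1))
        d$name <- paste0("dist", j)
        stack[[paste0("dist", j)]] <- d
      }
    }
    check_stack(stack)
  })
}

#' Sample species occurrences from an inhomogeneous point process
#'
#' Points are drawn by rejection sampling from an intensity proportional to
#' `exp(linear predictor)` of the stack layers (standardized to zero mean
#' and unit variance, so each coefficient is an effect per SD of its layer)
#' under each species' coefficient vector, mimicking multi-source presence
#' records (surveys, camera traps, roadkill, citizen science) clustered on
#' suitable habitat.
#' Each record carries a uniformly drawn date in the collection window and a
#' source label; `count` is 1.
#'
#' @param truth A `scenario_truth`; `species_coefficients` must cover every
#'   requested species.
#' @param stack Predictor stack (named list of `raster_grid`).
#' @param per_species_n Named integer vector/list: species -> number of
#'   points (> 0).
#' @param date_window Length-2 `Date` vector for record dates.
#' @param sources Candidate source labels sampled per record.
#' @return An occurrence tibble (see [occurrence_set()]): columns `species`,
#'   `x`, `y`, `date`, `source`, `count`.
#' @export
generate_occurrences <- function(truth, stack, per_species_n,
                                 date_window = as.Date(c("2023-03-01",
                                                         "2024-04-30")),
                                 sources = c("survey", "camera", "roadkill",
                                             "citizen")) {
  stopifnot(inherits(truth, "scenario_truth"))
  stack <- check_stack(stack)
  n <- unlist(per_species_n)
  stopifnot(all(n > 0))
  missing_sp <- setdiff(names(n), names(truth$species_coefficients))
  if (length(missing_sp)) {
    stop("no coefficients for species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  vals <- stack_values(stack)
  # coefficients act on standardized layers (per-SD effects), so a
  # distance layer in meters and a unit-variance field are comparable
  vals <- apply(vals, 2, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(v * 0)
    (v - mean(v, na.rm = TRUE)) / s
  })
  ext <- raster_extent(stack[[1]])
  withr::with_seed(truth$seed, {
    recs <- lapply(names(n), function(sp) {
      beta <- truth$species_coefficients[[sp]]
      stopifnot(length(beta) == ncol(vals))
      eta <- as.vector(vals %*% beta)
      lam <- exp(eta - max(eta, na.rm = TRUE))   # intensity scaled to max 1
      lam[is.na(lam)] <- 0
      if (!any(lam > 0)) stop("intensity identically zero", call. = FALSE)
      xs <- ys <- numeric(0)
      need <- n[[sp]]
      g <- stack[[1]]
      while (need > 0) {
        m <- max(need * 4L, 200L)
        px <- stats::runif(m, ext[["xmin"]], ext[["xmax"]])
        py <- stats::runif(m, ext[["ymin"]], ext[["ymax"]])
        rc <- cell_rowcol(g, px, py)
        idx <- (rc$row - 1L) * ncol(g$values) + rc$col
        keep <- !is.na(idx) & stats::runif(m) < lam[idx]
        xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
        need <- n[[sp]] - length(xs)
      }
      tibble::tibble(
        species = sp,
        x = xs[seq_len(n[[sp]])], y = ys[seq_len(n[[sp]])],
        date = date_window[1] +
          sample.int(as.integer(date_window[2] - date_window[1]) + 1L,
                     n[[sp]], replace = TRUE) - 1L,
        source = sample(sources, n[[sp]], replace = TRUE),
        count = 1L
      )
    })
    occurrence_set(dplyr::bind_rows(recs), crs = stack[[1]]$crs,
                   extent = ext)
  })
}

#' Simulate camera-trap encounters under the random encounter model
#'
#' Forward model of the REM: each camera accumulates detections over its
#' effort as a Poisson count with mean `t * D * v * r * (2 + theta) / pi`
#' (ideal-gas encounter rate with density D in ind/km^2, speed v in km/day,
#' detection radius r in km, angle theta in radians, effort t in days).
#' Camera positions are uniform over the scenario extent.
#'
#' @param truth A `scenario_truth` holding D, v, r, theta.
#' @param n_cameras Number of stations (>= 1).
#' @param effort_days Per-camera effort in days (scalar or length
#'   `n_cameras`), all > 0.
#' @param seed Integer seed (defaults to the scenario seed).
#' @return A camera tibble (see [camera_dataset()]): `id`, `x`, `y`,
#'   `effort`, `detections`, `radius`, `angle`.
#' @export
simulate_camera_encounters <- function(truth, n_cameras, effort_days,
                                       seed = truth$seed) {
  stopifnot(inherits(truth, "scenario_truth"), n_cameras >= 1)
  t_days <- rep_len(effort_days, n_cameras)
  if (any(t_days <= 0)) stop("effort must be positive", call. = FALSE)
  mu <- t_days * truth$true_density * truth$true_speed * truth$true_radius *
    (2 + truth$true_angle) / pi
  withr::with_seed(as.integer(seed), {
    camera_dataset(tibble::tibble(
      id = sprintf("cam%03d", seq_len(n_cameras)),
      x = stats::runif(n_cameras, truth$extent[1], truth$extent[3]),
      y = stats::runif(n_cameras, truth$extent[2], truth$extent[4]),
      effort = t_days,
      detections = stats::rpois(n_cameras, mu),
      radius = truth$true_radius,
      angle = truth$true_angle
    ))
  })
}

#' Write a full synthetic scenario to disk
#'
#' Occurrences as CSV, predictors as ESRI ASCII grids, and the ground truth
#' as a JSON sidecar, so a scenario can be round-tripped through the file
#' interfaces.
#'
#' @param truth A `scenario_truth`.
#' @param stack Predictor stack.
#' @param occ Occurrence tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(truth, stack, occ, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stack <- check_stack(stack)
  paths <- character(0)
  for (nm in names(stack)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack[[nm]], p)
    paths <- c(paths, p)
  }
  occ_path <- file.path(dir, "occurrences.csv")
  utils::write.csv(as.data.frame(occ), occ_path, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(unclass(truth), truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, occ_path, truth_path))
}
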