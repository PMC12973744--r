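#' Lightweight single-band georeferenced raster grid
#'
#' `raster_grid()` builds the container used throughout the package for
#' environmental predictors, bias layers and suitability maps: a rectangular
#' matrix of cell values plus the geotransform (origin, square cell size) and
#' a CRS tag. Row 1 of `values` is the northernmost row, matching on-disk
#' raster order; missing cells are `NA`.
#'
#' @param values Numeric matrix; row 1 is the top (north) row.
#' @param xmin,ymin Coordinates (meters, projected CRS) of the lower-left
#'   corner of the grid.
#' @param cell_size Cell edge length in meters (> 0).
#' @param crs Character CRS tag; records are expected in a projected CRS in
#'   meters (e.g. the UTM 33N used for the study area). No reprojection is
#'   performed anywhere in the package.
#' @param name Optional layer name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymin, cell_size, crs = "EPSG:32633",
                        name = "layer") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster must have at least one cell", call. = FALSE)
  }
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cell_size = as.numeric(cell_size), crs = crs, name = name),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  ext <- raster_extent(x)
  v <- x$values
  cat(sprintf("<raster_grid '%s'> %d x %d cells @ %g m [%s]\n",
              x$name, nrow(v), ncol(v), x$cell_size, x$crs))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              ext[["xmin"]], ext[["xmax"]], ext[["ymin"]], ext[["ymax"]]))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d NA\n", rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' Raster extent
#'
#' @param g A `raster_grid`.
#' @return Named numeric vector `xmin, ymin, xmax, ymax`.
#' @export
raster_extent <- function(g) {
  stopifnot(inherits(g, "raster_grid"))
  c(xmin = g$xmin, ymin = g$ymin,
    xmax = g$xmin + ncol(g$values) * g$cell_size,
    ymax = g$ymin + nrow(g$values) * g$cell_size)
}

#' Cell-center coordinates of every cell
#'
#' @param g A `raster_grid`.
#' @return Tibble with `x`, `y`, `row`, `col` in row-major order (top row
#'   first), matching `as.vector(t(g$values))`.
#' @export
raster_xy <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  ymax <- g$ymin + nr * g$cell_size
  tibble::tibble(
    row = rep(seq_len(nr), each = nc),
    col = rep(seq_len(nc), times = nr),
    x = g$xmin + (rep(seq_len(nc), times = nr) - 0.5) * g$cell_size,
    y = ymax - (rep(seq_len(nr), each = nc) - 0.5) * g$cell_size
  )
}

#' Raster values as a vector (row-major, top row first)
#' @param g A `raster_grid`.
#' @export
raster_values <- function(g) as.vector(t(g$values))

#' @export
as_tibble.raster_grid <- function(x, ...) {
  out <- raster_xy(x)
  out$value <- raster_values(x)
  out
}

# Row/col of the cell containing (x, y). Cells are half-open
# [x0, x0+cs) x [y0, y0+cs); points on the max edge are clamped into the
# last cell so the full closed extent is covered exactly once.
cell_rowcol <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  ymax <- g$ymin + nr * g$cell_size
  col <- floor((x - g$xmin) / g$cell_size) + 1
  row <- floor((ymax - y) / g$cell_size) + 1
  # clamp max-edge points; y == ymax maps to row 0 under the half-open rule
  col[x == g$xmin + nc * g$cell_size] <- nc
  row[y == ymax] <- 1
  inside <- x >= g$xmin & x <= g$xmin + nc * g$cell_size &
    y >= g$ymin & y <= ymax
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Extract raster values at point locations
#'
#' @param g A `raster_grid`.
#' @param x,y Numeric coordinate vectors.
#' @param method `"nearest"` (value of the containing cell) or `"bilinear"`
#'   (interpolation between the four surrounding cell centers; coordinates
#'   are clamped to the cell-center hull so constants are preserved at the
#'   edges).
#' @return Numeric vector; `NA` outside the grid.
#' @export
raster_extract <- function(g, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (method == "nearest") {
    rc <- cell_rowcol(g, x, y)
    out <- rep(NA_real_, length(x))
    ok <- rc$inside & !is.na(rc$row)
    out[ok] <- g$values[cbind(rc$row[ok], rc$col[ok])]
    return(out)
  }
  nr <- nrow(g$values); nc <- ncol(g$values)
  cs <- g$cell_size
  ymax <- g$ymin + nr * cs
  ext <- raster_extent(g)
  inside <- x >= ext[["xmin"]] & x <= ext[["xmax"]] &
    y >= ext[["ymin"]] & y <= ext[["ymax"]]
  # fractional column/row measured in cell-center units, clamped to hull
  fc <- pmin(pmax((x - g$xmin) / cs + 0.5, 1), nc)
  fr <- pmin(pmax((ymax - y) / cs + 0.5, 1), nr)
  c0 <- pmin(floor(fc), nc - 1); c0[nc == 1] <- 1
  r0 <- pmin(floor(fr), nr - 1); r0[nr == 1] <- 1
  wc <- fc - c0; wr <- fr - r0
  c1 <- pmin(c0 + 1, nc); r1 <- pmin(r0 + 1, nr)
  v00 <- g$values[cbind(r0, c0)]; v01 <- g$values[cbind(r0, c1)]
  v10 <- g$values[cbind(r1, c0)]; v11 <- g$values[cbind(r1, c1)]
  out <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
    wr * ((1 - wc) * v10 + wc * v11)
  out[!inside] <- NA_real_
  out
}

#' Read / write a raster as ESRI ASCII grid
#'
#' Plain-text raster interchange. `NODATA_value` cells become `NA` on read
#' and `NA` cells are written as the sentinel.
#'
#' @param path File path (`.asc`).
#' @param crs,name Metadata attached on read (the format itself carries none).
#' @return `read_ascii_grid()` returns a `raster_grid`.
#' @export
read_ascii_grid <- function(path, crs = "EPSG:32633", name = "layer") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, skip = length(lines), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  ymin <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  raster_grid(m, xmin, ymin, hdr$cellsize, crs = crs, name = name)
}

#' @rdname read_ascii_grid
#' @param g A `raster_grid` to write.
#' @param nodata Sentinel written for `NA` cells; must not collide with a
#'   legitimate value.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "raster_grid"))
  v <- g$values
  if (any(v == nodata, na.rm = TRUE)) {
    stop("nodata sentinel ", nodata, " occurs as a data value", call. = FALSE)
  }
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, digits = 12, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Align rasters onto a template grid by bilinear resampling
#'
#' Every raster is resampled onto the template's geotransform with bilinear
#' interpolation of cell-center values. A target cell whose interpolation
#' stencil touches any `NA` source cell, or that falls outside the source
#' extent, is `NA` in the output. Rasters already on the template geometry
#' are returned unchanged.
#'
#' @param rasters A list of `raster_grid` (or a single one).
#' @param template A `raster_grid` defining the target geometry.
#' @return List of aligned `raster_grid`s (same length/names as input).
#' @export
align_rasters <- function(rasters, template) {
  stopifnot(inherits(template, "raster_grid"))
  single <- inherits(rasters, "raster_grid")
  if (single) rasters <- list(rasters)
  te <- raster_extent(template)
  out <- lapply(rasters, function(src) {
    stopifnot(inherits(src, "raster_grid"))
    se <- raster_extent(src)
    if (se[["xmax"]] <= te[["xmin"]] || se[["xmin"]] >= te[["xmax"]] ||
        se[["ymax"]] <= te[["ymin"]] || se[["ymin"]] >= te[["ymax"]]) {
      stop("raster extent is disjoint from the template", call. = FALSE)
    }
    if (same_geometry(src, template)) return(src)
    xy <- raster_xy(template)
    vals <- raster_extract(src, xy$x, xy$y, method = "bilinear")
    m <- matrix(vals, nrow = nrow(template$values),
                ncol = ncol(template$values), byrow = TRUE)
    raster_grid(m, template$xmin, template$ymin, template$cell_size,
                crs = template$crs, name = src$name)
  })
  if (single) out[[1]] else out
}

#' Euclidean distance to the nearest cell of a land-cover class
#'
#' For every cell, the center-to-center Euclidean distance (meters) to the
#' nearest cell carrying `class_id`; class cells themselves hold 0. The
#' input must be categorical (integer-valued labels).
#'
#' @param landcover A `raster_grid` of integer class labels.
#' @param class_id The label of the source class.
#' @return A `raster_grid` of distances. If the class is absent the output
#'   is all-`NA` and a warning is raised.
#' @export
distance_to_class <- function(landcover, class_id) {
  stopifnot(inherits(landcover, "raster_grid"))
  v <- landcover$values
  fin <- v[!is.na(v)]
  if (length(fin) && any(abs(fin - round(fin)) > 1e-9)) {
    stop("land-cover raster must hold integer class labels", call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v); cs <- landcover$cell_size
  src <- which(!is.na(v) & v == class_id, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  if (nrow(src) == 0L) {
    warning("class ", class_id, " not present; returning all-NA distances")
  } else {
    tgt <- which(!is.na(v), arr.ind = TRUE)
    # all-pairs nearest scan in cell units; grids here are modest
    dr <- outer(tgt[, 1], src[, 1], "-")
    dc <- outer(tgt[, 2], src[, 2], "-")
    dmin <- sqrt(apply(dr * dr + dc * dc, 1, min))
    out[tgt] <- dmin * cs
  }
  raster_grid(out, landcover$xmin, landcover$ymin, cs, crs = landcover$crs,
              name = paste0("dist_class_", class_id))
}

#' Slope and aspect from a DEM (Horn 3x3 stencil)
#'
#' Slope in degrees; aspect in degrees clockwise from north. Aspect is `NA`
#' on flat cells; both are `NA` on the one-cell border and wherever the
#' stencil touches `NA`.
#'
#' @param dem A `raster_grid` of elevations (meters).
#' @return Named list with `slope` and `aspect` rasters.
#' @export
terrain_layers <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values; nr <- nrow(z); nc <- ncol(z); cs <- dem$cell_size
  slope <- aspect <- matrix(NA_real_, nr, nc)
  if (nr >= 3 && nc >= 3) {
    ri <- 2:(nr - 1); ci <- 2:(nc - 1)
    # Horn weights; rows run north->south so +row is -y
    a <- z[ri - 1, ci - 1]; b <- z[ri - 1, ci]; cc <- z[ri - 1, ci + 1]
    d <- z[ri, ci - 1];                      f <- z[ri, ci + 1]
    g_ <- z[ri + 1, ci - 1]; h <- z[ri + 1, ci]; i2 <- z[ri + 1, ci + 1]
    dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g_)) / (8 * cs)
    dzdy <- ((a + 2 * b + cc) - (g_ + 2 * h + i2)) / (8 * cs)
    sl <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    # downslope direction, degrees clockwise from north
    asp <- (atan2(dzdx, dzdy) * 180 / pi + 180) %% 360
    flat <- !is.na(dzdx) & !is.na(dzdy) & dzdx == 0 & dzdy == 0
    asp[flat] <- NA_real_
    slope[ri, ci] <- sl
    aspect[ri, ci] <- asp
  }
  list(
    slope = raster_grid(slope, dem$xmin, dem$ymin, cs, crs = dem$crs,
                        name = "slope"),
    aspect = raster_grid(aspect, dem$xmin, dem$ymin, cs, crs = dem$crs,
                         name = "aspect")
  )
}

#' Plot a raster grid with ggplot2
#'
#' @param object A `raster_grid`.
#' @param ... Unused.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble.raster_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "Easting (m)", y = "Northing (m)",
                  fill = object$name) +
    ggplot2::theme_minimal()
}

# stack helpers -----------------------------------------------------------

# a predictor stack is a named list of co-registered raster_grids
check_stack <- function(stack) {
  if (inherits(stack, "raster_grid")) stack <- list(stack)
  stopifnot(length(stack) >= 1L, all(vapply(stack, inherits, TRUE, "raster_grid")))
  tmpl <- stack[[1]]
  for (g in stack[-1]) {
    if (!same_geometry(g, tmpl)) {
      stop("stack layers are not co-registered; run align_rasters() first",
           call. = FALSE)
    }
  }
  if (is.null(names(stack)) || any(!nzchar(names(stack)))) {
    names(stack) <- vapply(stack, function(g) g$name, character(1))
  }
  stack
}

# cells x layers value matrix (row-major cell order), with cell coordinates
stack_values <- function(stack) {
  stack <- check_stack(stack)
  vals <- vapply(stack, raster_values, numeric(length(raster_values(stack[[1]]))))
  colnames(vals) <- names(stack)
  vals
}
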