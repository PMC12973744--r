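#' Occurrence set: validated multi-source presence records
#'
#' An occurrence set is a tibble with columns `species`, `x`, `y` (meters,
#' projected CRS), `date` (`Date`), `source`, `count` (positive integer),
#' plus a CRS tag and an optional declared extent carried as attributes.
#' All occurrence operations take and return this tibble, so they chain
#' with the pipe.
#'
#' @param records A data frame with the required columns.
#' @param crs CRS tag (projected, meters); validated, never reprojected.
#' @param extent Optional `c(xmin, ymin, xmax, ymax)`; records outside it
#'   are an error.
#' @return A tibble of class `occurrence_set`.
#' @export
occurrence_set <- function(records, crs = "EPSG:32633", extent = NULL) {
  need <- c("species", "x", "y", "date", "source", "count")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing occurrence columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(records)[, need]
  out$date <- as.Date(out$date)
  out$count <- as.integer(out$count)
  if (nrow(out)) {
    if (any(!is.finite(out$x) | !is.finite(out$y))) {
      stop("non-finite coordinates in occurrence records", call. = FALSE)
    }
    if (any(out$count < 1L)) stop("count must be >= 1", call. = FALSE)
    if (!is.null(extent)) {
      bad <- out$x < extent[1] | out$x > extent[3] |
        out$y < extent[2] | out$y > extent[4]
      if (any(bad)) {
        stop(sum(bad), " record(s) fall outside the declared extent",
             call. = FALSE)
      }
    }
  }
  attr(out, "crs") <- crs
  attr(out, "extent") <- extent
  class(out) <- c("occurrence_set", class(out))
  out
}

# tibble subsetting strips custom attrs; re-attach from a donor
restore_occ <- function(new, old) {
  occurrence_set(new, crs = attr(old, "crs"), extent = attr(old, "extent"))
}

#' Load occurrence records from CSV
#'
#' Parses `species, x, y, date, source, count`; rows with missing or
#' unparseable coordinates or dates are dropped, not fatal, and tallied in
#' a rejection report attached as attribute `"rejections"` (a tibble with
#' the offending row number and reason).
#'
#' @param path CSV file path.
#' @param crs CRS tag the coordinates are declared in.
#' @param extent Optional extent for validation of the kept records.
#' @return An `occurrence_set`; `attr(, "rejections")` holds the report.
#' @export
load_occurrences <- function(path, crs = "EPSG:32633", extent = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "x", "y", "date", "source", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  date <- as.Date(raw$date, format = "%Y-%m-%d", optional = TRUE)
  count <- suppressWarnings(as.integer(raw$count))
  count[is.na(count)] <- 1L  # absent/blank count defaults to one individual
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(x) | is.na(y)] <- "unparseable coordinates"
  reason[is.na(date)] <- "unparseable date"
  keep <- is.na(reason)
  rejections <- tibble::tibble(row = which(!keep), reason = reason[!keep])
  occ <- occurrence_set(
    tibble::tibble(species = raw$species[keep], x = x[keep], y = y[keep],
                   date = date[keep], source = raw$source[keep],
                   count = pmax(count[keep], 1L)),
    crs = crs, extent = extent
  )
  attr(occ, "rejections") <- rejections
  occ
}

#' Remove duplicate occurrence records
#'
#' A duplicate is a record sharing species, coordinates AND date with an
#' earlier record; the first in input order is kept. Records at the same
#' place on different dates are distinct observations and are all kept.
#'
#' @param occ An `occurrence_set`.
#' @return The deduplicated `occurrence_set`, input order preserved.
#' @export
deduplicate_occurrences <- function(occ) {
  stopifnot(inherits(occ, "occurrence_set"))
  if (!nrow(occ)) return(occ)
  key <- paste(occ$species, occ$x, occ$y, occ$date, sep = "\r")
  restore_occ(occ[!duplicated(key), ], occ)
}

#' Spatially thin occurrences to one record per species per grid cell
#'
#' Within each species, cells of the reference grid retain a single record:
#' the earliest date wins, ties broken by input order. Points falling
#' outside the grid are dropped and reported in the `"rejections"`
#' attribute. Cells are half-open `[x0, x0 + cs)`; points on the max edge
#' of the extent are clamped into the last cell.
#'
#' @param occ An `occurrence_set`.
#' @param grid A `raster_grid` defining the thinning resolution (typically
#'   the predictor grid, 100 m).
#' @return Thinned `occurrence_set`, a subsequence of the input.
#' @export
thin_to_grid <- function(occ, grid) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(grid, "raster_grid"))
  if (!nrow(occ)) return(occ)
  rc <- cell_rowcol(grid, occ$x, occ$y)
  outside <- !rc$inside | is.na(rc$row)
  rejections <- tibble::tibble(row = which(outside),
                               reason = "outside thinning grid")
  inb <- which(!outside)
  if (!length(inb)) {
    out <- restore_occ(occ[0, ], occ)
    attr(out, "rejections") <- rejections
    return(out)
  }
  cell <- (rc$row[inb] - 1L) * ncol(grid$values) + rc$col[inb]
  df <- tibble::tibble(orig = inb, cell = cell,
                       species = occ$species[inb], date = occ$date[inb])
  keep <- df |>
    dplyr::group_by(.data$species, .data$cell) |>
    dplyr::slice_min(.data$date, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$orig, n = 1) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$orig) |>
    sort()
  out <- restore_occ(occ[keep, ], occ)
  attr(out, "rejections") <- rejections
  out
}

#' Summarise an occurrence set
#'
#' @param object An `occurrence_set`.
#' @param ... Unused.
#' @return Tibble with per-species record counts, date range and sources.
#' @export
summary.occurrence_set <- function(object, ...) {
  tibble::as_tibble(object) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      first_date = min(.data$date),
      last_date = max(.data$date),
      n_sources = dplyr::n_distinct(.data$source),
      .groups = "drop"
    )
}

#' Plot occurrence points, optionally over a raster
#'
#' @param object An `occurrence_set`.
#' @param raster Optional `raster_grid` background.
#' @param ... Unused.
#' @export
autoplot.occurrence_set <- function(object, raster = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(raster)) {
    p <- p + ggplot2::geom_raster(
      data = as_tibble.raster_grid(raster),
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
      ggplot2::scale_fill_viridis_c(na.value = "grey90")
  }
  p + ggplot2::geom_point(
    data = tibble::as_tibble(object),
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$species),
    size = 0.8, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)") +
    ggplot2::theme_minimal()
}
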