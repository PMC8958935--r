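# 500 m usage grids: effort (minutes trawled) and record-weighted mean
# discard-proportion rasters on a metric grid over the study area.

#' Define a metric analysis grid over a study area
#'
#' Cells are `cell_size_m` squares in a local equirectangular projection
#' centred on the bbox (see [local_projection()]). The origin is the
#' projected bbox's south-west corner snapped down to the cell size, so a
#' given bbox always yields the same, reportable grid alignment. Cells are
#' half-open `[x, x + s) x [y, y + s)`.
#'
#' @param bbox named `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param cell_size_m cell edge, metres.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(bbox, cell_size_m = 500) {
  bbox <- validate_bbox(bbox)
  if (cell_size_m <= 0) stop("cell_size_m must be positive")
  proj <- local_projection(bbox)
  corners <- proj$project(bbox[c("lon_min", "lon_max")], bbox[c("lat_min", "lat_max")])
  x0 <- floor(min(corners[, 1]) / cell_size_m) * cell_size_m
  y0 <- floor(min(corners[, 2]) / cell_size_m) * cell_size_m
  n_cols <- ceiling((max(corners[, 1]) - x0) / cell_size_m)
  n_rows <- ceiling((max(corners[, 2]) - y0) / cell_size_m)
  structure(list(bbox = bbox, proj = proj, cell_size_m = cell_size_m,
                 origin_x = x0, origin_y = y0,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %d x %d cells of %g m, origin (%.0f, %.0f) m>\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$origin_x, x$origin_y))
  invisible(x)
}

# row/col (row 1 = southernmost) of projected points; NA outside the grid
cell_index <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size_m) + 1
  row <- floor((y - spec$origin_y) / spec$cell_size_m) + 1
  out <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  col[out] <- NA; row[out] <- NA
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell centroids of a grid
#'
#' @param spec a [grid_spec()].
#' @return data.frame `row`, `col`, `easting`, `northing` (projected metres)
#'   and `lon`, `lat` of each cell centre.
#' @export
cell_centroids <- function(spec) {
  g <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  g$easting <- spec$origin_x + (g$col - 0.5) * spec$cell_size_m
  g$northing <- spec$origin_y + (g$row - 0.5) * spec$cell_size_m
  ll <- spec$proj$unproject(g$easting, g$northing)
  g$lon <- ll[, "lon"]; g$lat <- ll[, "lat"]
  g
}

new_usage_grid <- function(spec, values, variable, reporter = NA, period = NA,
                           n_outside = 0L) {
  structure(list(spec = spec, values = values, variable = variable,
                 reporter = reporter, period = period, n_outside = n_outside),
            class = "usage_grid")
}

#' @export
print.usage_grid <- function(x, ...) {
  nv <- sum(!is.na(x$values))
  cat(sprintf("<usage_grid [%s]: %d x %d cells, %d non-missing%s%s>\n",
              x$variable, x$spec$n_rows, x$spec$n_cols, nv,
              if (!is.na(x$reporter)) paste0(", reporter ", x$reporter) else "",
              if (!is.na(x$period)) paste0(", period ", x$period) else ""))
  if (nv) cat(sprintf("  range %.3g .. %.3g; %d fixes fell outside the grid\n",
                      min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
                      x$n_outside))
  invisible(x)
}

#' @export
as.data.frame.usage_grid <- function(x, ..., drop_missing = TRUE) {
  g <- cell_centroids(x$spec)
  g$value <- x$values[cbind(g$row, g$col)]
  if (drop_missing) g <- g[!is.na(g$value), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Rasterize trawling fixes into an effort grid
#'
#' Each fix classified as trawling contributes `fix_minutes` (the position
#' cadence) to its cell: cell value = fix count x 3 minutes. Unfished cells
#' are missing (`NA`), distinct from an observed zero. Fixes outside the grid
#' are counted in `n_outside`.
#'
#' @param fixes data.frame with `lon`, `lat` of trawling fixes.
#' @param spec a [grid_spec()].
#' @param fix_minutes minutes represented by one fix.
#' @param reporter,period metadata carried on the grid.
#' @return a `usage_grid` with `variable = "effort_minutes"`.
#' @export
rasterize_effort <- function(fixes, spec, fix_minutes = 3, reporter = NA, period = NA) {
  vals <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  if (is.null(fixes) || nrow(fixes) == 0) {
    warning("no trawling fixes to rasterize: all-missing effort grid")
    return(new_usage_grid(spec, vals, "effort_minutes", reporter, period))
  }
  xy <- spec$proj$project(fixes$lon, fixes$lat)
  idx <- cell_index(spec, xy[, 1], xy[, 2])
  inside <- !is.na(idx$row)
  if (any(inside)) {
    tab <- table(paste(idx$row[inside], idx$col[inside]))
    rc <- do.call(rbind, strsplit(names(tab), " "))
    vals[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <- as.numeric(tab) * fix_minutes
  }
  new_usage_grid(spec, vals, "effort_minutes", reporter, period,
                 n_outside = sum(!inside))
}

#' Rasterize per-trip discard proportions carried on trawling fixes
#'
#' Each trip's discard proportion is assigned to each of its trawling fixes;
#' a cell's value is the mean over the fixes in it — i.e. trip contributions
#' weighted by their fix counts. Fixes lacking a `dp` are excluded and
#' counted.
#'
#' @param fixes data.frame with `lon`, `lat`, `dp` (the trip's discard
#'   proportion repeated on its fixes).
#' @inheritParams rasterize_effort
#' @return a `usage_grid` with `variable = "discard_proportion"` (also
#'   carries `n_no_dp`).
#' @export
rasterize_discards <- function(fixes, spec, reporter = NA, period = NA) {
  vals <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  if (is.null(fixes) || nrow(fixes) == 0) {
    warning("no fixes to rasterize: all-missing discard grid")
    return(new_usage_grid(spec, vals, "discard_proportion", reporter, period))
  }
  n_no_dp <- sum(is.na(fixes$dp))
  fixes <- fixes[!is.na(fixes$dp), , drop = FALSE]
  xy <- spec$proj$project(fixes$lon, fixes$lat)
  idx <- cell_index(spec, xy[, 1], xy[, 2])
  inside <- !is.na(idx$row)
  if (any(inside)) {
    key <- paste(idx$row[inside], idx$col[inside])
    m <- tapply(fixes$dp[inside], key, mean)
    rc <- do.call(rbind, strsplit(names(m), " "))
    vals[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <- as.numeric(m)
  }
  g <- new_usage_grid(spec, vals, "discard_proportion", reporter, period,
                      n_outside = sum(!inside))
  g$n_no_dp <- n_no_dp
  g
}

#' Min-max normalize a usage grid to [0, 1]
#'
#' `(value - min) / (max - min)` over non-missing cells; missing cells stay
#' missing. A constant grid maps to 0 everywhere (keeps downstream map
#' comparison defined).
#'
#' @param grid a `usage_grid`.
#' @return a `usage_grid` with `variable = "normalized"`.
#' @export
normalize_grid <- function(grid) {
  stopifnot(inherits(grid, "usage_grid"))
  v <- grid$values
  if (all(is.na(v))) stop("cannot normalize an all-missing grid")
  rng <- range(v, na.rm = TRUE)
  v <- if (diff(rng) == 0) ifelse(is.na(v), NA_real_, 0) else (v - rng[1]) / diff(rng)
  out <- grid
  out$values <- v
  out$variable <- "normalized"
  out$normalized_from <- grid$variable
  out
}

#' Pool usage grids by elementwise sum
#'
#' Sums values across grids on the same spec, treating missing as absent: a
#' cell is missing in the result only if missing in every input. Appropriate
#' for effort grids (minutes add); for discard grids build the pooled grid
#' from the pooled fixes instead.
#'
#' @param grids list of `usage_grid`s sharing a spec.
#' @export
combine_grids <- function(grids) {
  stopifnot(length(grids) >= 1)
  dims <- vapply(grids, function(g) c(g$spec$n_rows, g$spec$n_cols), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("grids do not share a spec")
  acc <- grids[[1]]$values
  for (g in grids[-1]) {
    v <- g$values
    both <- !is.na(acc) & !is.na(v)
    acc[both] <- acc[both] + v[both]
    only_new <- is.na(acc) & !is.na(v)
    acc[only_new] <- v[only_new]
  }
  new_usage_grid(grids[[1]]$spec, acc, grids[[1]]$variable,
                 reporter = grids[[1]]$reporter, period = "pooled")
}
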