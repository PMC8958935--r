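# Similarity-in-means comparison of two usage maps: local 3x3 neighbourhood
# means, per-cell similarity 1 - |mA - mB|, overall index = mean over valid
# cells. Inputs must be on a common grid and scaled to [0, 1].

#' Neighbourhood means of a grid
#'
#' Replaces each cell by the mean of the `window x window` block centred on
#' it, truncated to in-grid cells at edges (a corner averages itself and its
#' three in-grid neighbours... for `window = 3`, four cells). Missing cells
#' are handled per `fill`: `"zero"` (default) counts them as 0 usage with the
#' full in-grid denominator; `"drop"` averages non-missing neighbours only
#' (cells with no non-missing neighbour become `NA`).
#'
#' @param values numeric matrix (grid values) or a `usage_grid`.
#' @param window odd neighbourhood size.
#' @param fill `"zero"` or `"drop"`.
#' @return numeric matrix of local means.
#' @export
local_means <- function(values, window = 3, fill = c("zero", "drop")) {
  fill <- match.arg(fill)
  if (inherits(values, "usage_grid")) values <- values$values
  if (window %% 2 == 0 || window < 1) stop("window must be an odd positive integer")
  h <- (window - 1) / 2
  nr <- nrow(values); nc <- ncol(values)
  v0 <- values
  v0[is.na(v0)] <- 0
  # running sums over rows then cols (edge-truncated box filter)
  csum <- function(m) {
    # cumulative trick per dimension, denominator-aware
    out_s <- matrix(0, nrow(m), ncol(m))
    out_n <- matrix(0, nrow(m), ncol(m))
    for (dr in -h:h) {
      rows <- seq_len(nrow(m)) + dr
      ok <- rows >= 1 & rows <= nrow(m)
      out_s[ok, ] <- out_s[ok, ] + m[rows[ok], , drop = FALSE]
      out_n[ok, ] <- out_n[ok, ] + 1
    }
    list(s = out_s, n = out_n)
  }
  rowpass_s <- csum(v0)
  rowpass_w <- csum(matrix(as.numeric(!is.na(values)), nr, nc))  # non-NA counts
  colpass <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    cnt <- matrix(0, nrow(m), ncol(m))
    for (dc in -h:h) {
      cols <- seq_len(ncol(m)) + dc
      ok <- cols >= 1 & cols <= ncol(m)
      out[, ok] <- out[, ok] + m[, cols[ok], drop = FALSE]
      cnt[, ok] <- cnt[, ok] + 1
    }
    list(s = out, n = cnt)
  }
  S <- colpass(rowpass_s$s)$s               # windowed sum of values (NA as 0)
  NN <- colpass(rowpass_s$n)$s              # in-grid cell count per window
  W <- colpass(rowpass_w$s)$s               # non-missing cell count per window
  if (fill == "zero") {
    S / NN
  } else {
    out <- S / W
    out[W == 0] <- NA_real_
    out
  }
}

#' Similarity-in-means index between two usage maps
#'
#' For each valid cell i, the local `window x window` means `mA(i)` and
#' `mB(i)` are compared as `s(i) = 1 - |mA(i) - mB(i)|`; the overall index is
#' the unweighted mean of `s(i)` over valid cells. With inputs in `[0, 1]`
#' (min-max-normalized effort or discard proportions) the index runs from 0
#' (dissimilar local means) to 1 (similarly high or low local usage). The
#' index is symmetric in its arguments and equals 1 for identical maps.
#'
#' @param grid_a,grid_b `usage_grid`s on the same spec (or plain matrices of
#'   equal dimension), values in `[0, 1]`.
#' @param window odd neighbourhood size (3 = the 3x3 default).
#' @param valid_rule `"either"` (default): a cell is valid when at least one
#'   map is non-missing there; `"both"`: both maps must be non-missing.
#' @param fill missing-cell policy inside windows, see [local_means()].
#' @return a `sim_index_result`: per-cell similarity matrix, `index`,
#'   `n_valid`.
#' @export
sim_index <- function(grid_a, grid_b, window = 3,
                      valid_rule = c("either", "both"),
                      fill = c("zero", "drop")) {
  valid_rule <- match.arg(valid_rule)
  fill <- match.arg(fill)
  va <- if (inherits(grid_a, "usage_grid")) grid_a$values else grid_a
  vb <- if (inherits(grid_b, "usage_grid")) grid_b$values else grid_b
  if (!all(dim(va) == dim(vb))) stop("grids have mismatched dimensions")
  if (inherits(grid_a, "usage_grid") && inherits(grid_b, "usage_grid")) {
    sa <- grid_a$spec; sb <- grid_b$spec
    if (sa$cell_size_m != sb$cell_size_m || sa$origin_x != sb$origin_x ||
        sa$origin_y != sb$origin_y)
      stop("grids have mismatched specs")
  }
  valid <- if (valid_rule == "either") !is.na(va) | !is.na(vb) else !is.na(va) & !is.na(vb)
  if (!any(valid)) stop("no valid cells to compare")
  rng <- range(c(va, vb), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("sim_index expects values in [0, 1]; normalize first")
  ma <- local_means(va, window, fill)
  mb <- local_means(vb, window, fill)
  s <- 1 - abs(ma - mb)
  s[!valid] <- NA_real_
  ok <- valid & !is.na(s)
  if (!any(ok)) stop("no valid cells with defined local means")
  structure(list(similarity = s, index = mean(s[ok]), n_valid = sum(ok),
                 window = window, valid_rule = valid_rule, fill = fill),
            class = "sim_index_result")
}

#' @export
print.sim_index_result <- function(x, ...) {
  cat(sprintf("<sim_index: %.3f over %d valid cells (%dx%d window, valid=%s, fill=%s)>\n",
              x$index, x$n_valid, x$window, x$window, x$valid_rule, x$fill))
  invisible(x)
}

#' Monthly and pooled similarity indices
#'
#' Computes the index per month for months where both reporters have a grid
#' (others are skipped with a warning), plus a pooled-period index on grids
#' aggregated over the whole period. Raw (un-normalized) grids are min-max
#' normalized before comparison when `normalize = TRUE`. Pooled grids default
#' to the elementwise sum across months (right for effort; for discard grids
#' pass explicit `pooled_a` / `pooled_b` built from all fixes).
#'
#' @param grids_a,grids_b named lists of `usage_grid`s keyed by month, one
#'   reporter each.
#' @param pooled_a,pooled_b optional whole-period grids.
#' @param normalize min-max normalize each grid before comparing.
#' @param ... passed to [sim_index()].
#' @return data.frame `period`, `index`, `n_valid` (months plus `"pooled"`).
#' @export
sim_by_period <- function(grids_a, grids_b, pooled_a = NULL, pooled_b = NULL,
                          normalize = TRUE, ...) {
  months <- intersect(names(grids_a), names(grids_b))
  skipped <- setdiff(union(names(grids_a), names(grids_b)), months)
  if (length(skipped))
    warning("months with one reporter only skipped: ", paste(skipped, collapse = ", "))
  if (length(months) == 0) stop("no month has grids from both reporters")
  prep <- function(g) if (normalize) normalize_grid(g) else g
  rows <- lapply(sort(months), function(m) {
    r <- sim_index(prep(grids_a[[m]]), prep(grids_b[[m]]), ...)
    data.frame(period = m, index = r$index, n_valid = r$n_valid)
  })
  if (is.null(pooled_a)) pooled_a <- combine_grids(grids_a[sort(months)])
  if (is.null(pooled_b)) pooled_b <- combine_grids(grids_b[sort(months)])
  rp <- sim_index(prep(pooled_a), prep(pooled_b), ...)
  out <- rbind(do.call(rbind, rows),
               data.frame(period = "pooled", index = rp$index, n_valid = rp$n_valid))
  rownames(out) <- NULL
  out
}
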