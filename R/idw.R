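# Inverse-distance-weighted interpolation onto regular grids, and an
# Esri ASCII grid writer.

#' Inverse-distance-weighted prediction at one or more points
#'
#' Predicts `Z*(x0) = sum(phi_i * Z(x_i))` where the weight of sample i is
#' `d_i^-power` renormalized to sum to one over the `k` nearest samples.
#' A target closer than 1e-9 m to a sample returns that sample's value
#' exactly (IDW is an exact interpolator).
#'
#' @param target Numeric `c(x, y)`, or a two-column matrix of targets.
#' @param coords Two-column matrix (x, y) of sample locations, meters.
#' @param values Numeric vector of sample values, one per row of `coords`.
#' @param power Positive distance-decay exponent (default 2).
#' @param k Number of nearest samples used, or `"all"` (default 12,
#'   capped at the number of samples).
#' @return Numeric vector of predictions, one per target.
#' @examples
#' coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
#' idw_predict(c(0.25, 0), coords, c(10, 20, 30))
#' @export
idw_predict <- function(target, coords, values, power = 2, k = 12) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty sample set", call. = FALSE)
  if (length(values) != nrow(coords)) {
    stop("values must match coords rows", call. = FALSE)
  }
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  if (identical(k, "all")) k <- nrow(coords)
  k <- min(as.integer(k), nrow(coords))
  if (is.null(dim(target))) target <- matrix(target, ncol = 2, byrow = TRUE)

  apply(target, 1, function(p) {
    d <- sqrt((coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2)
    hit <- which(d < 1e-9)
    if (length(hit) > 0) return(values[hit[1]])
    near <- order(d)[seq_len(k)]
    w <- d[near]^(-power)
    sum(w * values[near]) / sum(w)
  })
}

#' Interpolate a sample field onto a regular grid
#'
#' Runs [idw_predict()] at every cell center of a regular raster. Values
#' are stored row-major from the top-left cell (northernmost row first)
#' while the grid is georeferenced from its lower-left corner, matching
#' the Esri ASCII grid layout.
#'
#' @param samples A data.frame with `x`, `y` and the column named by
#'   `field` (a sample table or a per-sample capacity table).
#' @param field Name of the column to interpolate.
#' @param grid Grid spec: list with `origin_x`, `origin_y` (lower-left
#'   corner, meters), `cell_size`, `n_rows`, `n_cols`.
#' @param power,k Passed to [idw_predict()].
#' @return An object of class `idw_grid`: the grid spec plus a
#'   `n_rows x n_cols` matrix `values` (top row first) and the `field`
#'   name.
#' @export
rasterize_idw <- function(samples, field, grid, power = 2, k = 12) {
  grid <- validate_grid_spec(grid)
  stopifnot(all(c("x", "y", field) %in% names(samples)))
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)

  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  # row 1 of the matrix is the top (northernmost) row of cell centers
  ys <- grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) *
    grid$cell_size
  targets <- cbind(rep(xs, times = grid$n_rows),
                   rep(ys, each = grid$n_cols))
  z <- idw_predict(targets, cbind(samples$x, samples$y), samples[[field]],
                   power = power, k = k)
  structure(
    c(grid, list(
      values = matrix(z, nrow = grid$n_rows, ncol = grid$n_cols,
                      byrow = TRUE),
      field = field
    )),
    class = "idw_grid"
  )
}

#' @export
print.idw_grid <- function(x, ...) {
  cat(sprintf("IDW grid of '%s': %d x %d cells of %g m, origin (%g, %g)\n",
              x$field, x$n_rows, x$n_cols, x$cell_size,
              x$origin_x, x$origin_y))
  cat(sprintf("value range: [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write an interpolated grid as an Esri ASCII raster
#'
#' Plain-text `.asc` with the standard six-line header; values at six
#' significant digits, top row first.
#'
#' @param grid An `idw_grid` from [rasterize_idw()].
#' @param path Output file path.
#' @param nodata Sentinel written for non-finite cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "idw_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin_x, scientific = FALSE)),
    paste("yllcorner", format(grid$origin_y, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  vals <- grid$values
  vals[!is.finite(vals)] <- nodata
  for (r in seq_len(grid$n_rows)) {
    writeLines(paste(signif(vals[r, ], 6), collapse = " "), con)
  }
  invisible(path)
}
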