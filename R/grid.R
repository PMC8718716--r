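#' Grid transform between raster indices and projected coordinates
#'
#' A minimal north-up affine transform. Column `j`, row `i` (1-based, row 1
#' at the top/north) map to the pixel-centre coordinates
#' `x = x0 + (j - 1/2) * cell`, `y = y0 - (i - 1/2) * cell`, with `(x0, y0)`
#' the projected coordinates of the top-left corner of the raster and `cell`
#' the pixel size in metres.
#'
#' @param x0,y0 top-left corner of the grid, projected metres
#' @param cell pixel size in metres (> 0)
#' @param nrow,ncol raster dimensions
#' @return an object of class `grid_transform`
#' @export
grid_transform <- function(x0, y0, cell, nrow, ncol) {
  stopifnot(is.numeric(cell), length(cell) == 1L, cell > 0,
            nrow >= 1L, ncol >= 1L)
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0),
                 cell = as.numeric(cell),
                 nrow = as.integer(nrow), ncol = as.integer(ncol)),
            class = "grid_transform")
}

#' Pixel-centre coordinates of raster cells
#'
#' @param tr a [grid_transform()]
#' @param i,j row and column indices (vectorized, recycled)
#' @return list with numeric vectors `x`, `y`
#' @export
cell_center <- function(tr, i, j) {
  list(x = tr$x0 + (j - 0.5) * tr$cell,
       y = tr$y0 - (i - 0.5) * tr$cell)
}

#' Raster cell containing a projected point
#'
#' Inverse of [cell_center()]: the cell whose footprint contains `(x, y)`.
#' Points outside the raster return `NA` indices.
#'
#' @inheritParams cell_center
#' @param x,y projected coordinates, metres
#' @return list with integer vectors `i` (row), `j` (column)
#' @export
point_to_cell <- function(tr, x, y) {
  j <- as.integer(floor((x - tr$x0) / tr$cell)) + 1L
  i <- as.integer(floor((tr$y0 - y) / tr$cell)) + 1L
  bad <- i < 1L | i > tr$nrow | j < 1L | j > tr$ncol
  i[bad] <- NA_integer_
  j[bad] <- NA_integer_
  list(i = i, j = j)
}

#' Matrices of all pixel-centre coordinates
#'
#' @inheritParams cell_center
#' @return list of two `nrow x ncol` matrices `x` and `y`
#' @keywords internal
grid_centers <- function(tr) {
  xs <- tr$x0 + (seq_len(tr$ncol) - 0.5) * tr$cell
  ys <- tr$y0 - (seq_len(tr$nrow) - 0.5) * tr$cell
  list(x = matrix(xs, tr$nrow, tr$ncol, byrow = TRUE),
       y = matrix(ys, tr$nrow, tr$ncol))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

#' Linear-interpolation quantile
#'
#' The quantile rule used everywhere in the package: linear interpolation
#' between order statistics (R's type 7). Exposed so the rule is auditable.
#'
#' @param x numeric values (NAs removed)
#' @param probs probabilities in (0, 1)
#' @return numeric vector of quantiles
#' @export
quantile_linear <- function(x, probs) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to take a quantile of")
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. Keeps every generator reproducible without
# clobbering the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic derived seed < 2^31, so one experiment seed can drive
# independent stages without stream overlap.
derive_seed <- function(seed, tag) {
  h <- 5381
  for (k in utf8ToInt(paste0(tag, ":", seed))) h <- (h * 33 + k) %% 2147483629
  as.integer(h)
}

#' Parse and format ISO 8601 UTC timestamps
#'
#' @param x character timestamps, `YYYY-MM-DDTHH:MM:SSZ` or
#'   `YYYY-MM-DD HH:MM:SS`
#' @return `POSIXct` in UTC; `NA` where unparseable
#' @export
parse_utc <- function(x) {
  x <- sub("Z$", "", sub("T", " ", x))
  x <- ifelse(grepl("^\\d{4}-\\d{2}-\\d{2}$", x), paste0(x, " 00:00:00"), x)
  # elementwise fallback across formats (as.POSIXct's tryFormats is
  # all-or-nothing over a vector)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  retry <- is.na(out) & !is.na(x)
  if (any(retry))
    out[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d %H:%M", tz = "UTC"))
  out
}

#' @rdname parse_utc
#' @param t a `POSIXct`
#' @export
format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
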