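#' Lake outline polygon
#'
#' A simple planar polygon in projected metre coordinates: a two-column
#' matrix of ring vertices (not repeated at the end). All geometry in the
#' package is planar; there is no geodesic handling.
#'
#' @param coords numeric matrix with columns x, y (>= 3 vertices)
#' @return object of class `lake_polygon`
#' @export
lake_polygon <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) >= 2L && all(coords[1L, ] == coords[nrow(coords), ]))
    coords <- coords[-nrow(coords), , drop = FALSE]
  if (nrow(coords) > 0L && nrow(coords) < 3L)
    stop("a polygon needs at least 3 vertices")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  structure(coords, class = "lake_polygon")
}

poly_coords <- function(poly) {
  m <- unclass(poly)
  attr(m, "buffer_distance") <- NULL
  attr(m, "source_ring") <- NULL
  m
}

#' Shoelace area of a polygon
#'
#' @param poly a [lake_polygon()]
#' @return area in square metres (0 for an empty polygon)
#' @export
polygon_area <- function(poly) {
  v <- poly_coords(poly)
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  abs(sum(x * y2 - x2 * y)) / 2
}

# Even-odd point-in-polygon, vectorized over points.
ray_cast_inside <- function(ring, px, py) {
  n <- nrow(ring)
  if (n < 3L) return(rep(FALSE, length(px)))
  inside <- rep(FALSE, length(px))
  x <- ring[, 1L]; y <- ring[, 2L]
  jx <- c(x[n], x[-n]); jy <- c(y[n], y[-n])
  for (k in seq_len(n)) {
    crosses <- ((y[k] > py) != (jy[k] > py))
    if (any(crosses)) {
      xin <- (jx[k] - x[k]) * (py[crosses] - y[k]) / (jy[k] - y[k]) + x[k]
      inside[crosses] <- xor(inside[crosses], px[crosses] < xin)
    }
  }
  inside
}

# Minimum distance from points to the polygon boundary (all edges).
boundary_distance <- function(ring, px, py) {
  n <- nrow(ring)
  d2 <- rep(Inf, length(px))
  x <- ring[, 1L]; y <- ring[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  for (k in seq_len(n)) {
    ex <- x2[k] - x[k]; ey <- y2[k] - y[k]
    len2 <- ex * ex + ey * ey
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x[k]) * ex + (py - y[k]) * ey) / len2)) else 0
    dx <- px - (x[k] + t * ex); dy <- py - (y[k] + t * ey)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Point-in-polygon test
#'
#' For a buffered polygon produced by [buffer_shoreline()] the test is the
#' exact erosion criterion (inside the source outline and at least the
#' buffer distance from its boundary), which is the mathematical definition
#' of the inward offset and immune to offset-curve artefacts.
#'
#' @param poly a [lake_polygon()]
#' @param x,y point coordinates (vectorized)
#' @return logical vector
#' @export
polygon_contains <- function(poly, x, y) {
  src <- attr(poly, "source_ring")
  if (!is.null(src)) {
    d <- attr(poly, "buffer_distance")
    ray_cast_inside(src, x, y) & boundary_distance(src, x, y) >= d
  } else {
    ray_cast_inside(poly_coords(poly), x, y)
  }
}

# Cheap self-intersection screen: consecutive duplicate vertices or
# degenerate (zero-area) rings are rejected; full O(n^2) segment tests are
# not needed for the smooth outlines this package produces or reads.
validate_polygon <- function(poly) {
  v <- poly_coords(poly)
  if (nrow(v) == 0L) stop("empty polygon")
  if (anyNA(v)) stop("polygon contains non-finite vertices")
  dup <- which(rowSums((v - rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]))^2) == 0)
  if (length(dup)) stop("invalid polygon topology: repeated consecutive vertices")
  if (polygon_area(poly) <= 0) stop("invalid polygon topology: zero area")
  invisible(TRUE)
}

#' Inward shoreline buffer (polygon erosion)
#'
#' Erodes the lake outline by `distance` metres, the shoreline buffer that
#' removes mixed land--water pixels and adjacency-affected water. The
#' returned polygon's ring is the inward offset of the (densified) source
#' ring; its membership test ([polygon_contains()]) uses the exact erosion
#' criterion against the source outline. An empty result (small lake) is
#' returned as a zero-vertex polygon with a warning, not dropped silently.
#'
#' @param poly a [lake_polygon()]
#' @param distance buffer width in metres (>= 0); default 120
#' @return a `lake_polygon`, possibly empty
#' @export
buffer_shoreline <- function(poly, distance = 120) {
  stopifnot(is.numeric(distance), length(distance) == 1L, distance >= 0)
  validate_polygon(poly)
  if (distance == 0) return(poly)
  ring <- poly_coords(poly)
  n <- nrow(ring)
  # orientation: signed area > 0 means counter-clockwise
  x <- ring[, 1L]; y <- ring[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  ccw <- sum(x * y2 - x2 * y) / 2 > 0
  xp <- c(x[n], x[-n]); yp <- c(y[n], y[-n])   # previous vertex
  tx <- x2 - xp; ty <- y2 - yp                  # central-difference tangent
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  # inward normal: rotate the tangent by +90 for a ccw ring, -90 for cw
  s <- if (ccw) -1 else 1
  nx <- s * ty / len; ny <- -s * tx / len
  ox <- x + distance * nx; oy <- y + distance * ny
  # offset points sit up to a chord-sagitta short of the exact distance on
  # a densified curved ring; tolerate one edge length in the keep filter
  # (self-intersection artefacts undershoot by far more than that)
  tol <- max(sqrt((x2 - x)^2 + (y2 - y)^2))
  keep <- ray_cast_inside(ring, ox, oy) &
    boundary_distance(ring, ox, oy) >= distance - tol
  if (sum(keep) < 3L) {
    warning("shoreline buffer of ", distance, " m leaves no interior: empty polygon")
    out <- lake_polygon(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  } else {
    out <- lake_polygon(cbind(ox[keep], oy[keep]))
  }
  attr(out, "source_ring") <- ring
  attr(out, "buffer_distance") <- distance
  out
}

#' Secchi-based exclusion depth
#'
#' The depth threshold below which bottom reflectance may contaminate the
#' water-leaving signal: the `q`-quantile (default 95%) of all Secchi-depth
#' measurements of the lake, under the linear-interpolation quantile rule
#' ([quantile_linear()]).
#'
#' @param secchi_samples Secchi depths in metres (>= 1 value)
#' @param q quantile level in (0, 1); default 0.95
#' @return exclusion depth in metres
#' @export
secchi_exclusion_depth <- function(secchi_samples, q = 0.95) {
  secchi_samples <- secchi_samples[!is.na(secchi_samples)]
  if (length(secchi_samples) < 1L) stop("at least one Secchi sample required")
  if (!(q > 0 && q < 1)) stop("quantile level must be in (0, 1)")
  if (any(secchi_samples <= 0)) stop("Secchi depths must be positive")
  quantile_linear(secchi_samples, q)
}

#' Lake geometry container
#'
#' Bundles the lake outline, raster lake mask, bathymetry (metres, positive
#' down, 0 outside the lake) and grid transform; [build_valid_water_mask()]
#' derives and attaches the valid-water mask.
#'
#' @param polygon a [lake_polygon()]
#' @param lake_mask logical matrix
#' @param bathymetry numeric matrix, same dimensions
#' @param transform a [grid_transform()]
#' @return object of class `lake_geometry`
#' @export
lake_geometry <- function(polygon, lake_mask, bathymetry, transform) {
  stopifnot(inherits(polygon, "lake_polygon"),
            is.matrix(lake_mask), is.matrix(bathymetry),
            inherits(transform, "grid_transform"))
  if (!all(dim(lake_mask) == dim(bathymetry)))
    stop("lake_mask and bathymetry are on different grids")
  if (!all(dim(lake_mask) == c(transform$nrow, transform$ncol)))
    stop("rasters do not match the grid transform")
  if (any(bathymetry < 0)) stop("bathymetry must be >= 0 (positive down)")
  if (any(bathymetry[!lake_mask] != 0))
    stop("bathymetry must be 0 outside the lake mask")
  structure(list(polygon = polygon, lake_mask = lake_mask,
                 bathymetry = bathymetry, transform = transform,
                 valid_water_mask = NULL),
            class = "lake_geometry")
}

#' Build the valid-water mask
#'
#' A pixel is valid water iff its centre lies inside the lake outline eroded
#' by `buffer_distance` (shoreline buffer) AND its bottom depth is at least
#' the Secchi-based exclusion depth ([secchi_exclusion_depth()]). This mask
#' is the raster behind the `SHORE_SHALLOW_BUFFER` "+" flag.
#'
#' @param geometry a [lake_geometry()]
#' @param secchi_samples Secchi depths in metres
#' @param buffer_distance shoreline buffer in metres, default 120
#' @param secchi_quantile quantile level, default 0.95
#' @return logical matrix with attributes `exclusion_depth_m`,
#'   `buffer_distance_m` and `quantile_rule` ("linear_interpolation")
#' @export
build_valid_water_mask <- function(geometry, secchi_samples,
                                   buffer_distance = 120,
                                   secchi_quantile = 0.95) {
  stopifnot(inherits(geometry, "lake_geometry"))
  depth_excl <- secchi_exclusion_depth(secchi_samples, secchi_quantile)
  buffered <- buffer_shoreline(geometry$polygon, buffer_distance)
  ctr <- grid_centers(geometry$transform)
  inside <- matrix(polygon_contains(buffered, as.vector(ctr$x), as.vector(ctr$y)),
                   nrow(geometry$lake_mask), ncol(geometry$lake_mask))
  mask <- geometry$lake_mask & inside & (geometry$bathymetry >= depth_excl)
  if (!any(mask))
    warning("valid-water mask is empty (exclusion depth ", round(depth_excl, 2),
            " m exceeds all lake depths inside the buffer)")
  structure(mask, exclusion_depth_m = depth_excl,
            buffer_distance_m = buffer_distance,
            quantile_rule = "linear_interpolation")
}
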