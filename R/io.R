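# Numeric serialization: %.17g round-trips IEEE doubles exactly, so every
# writer/reader pair below is bit-lossless for finite values.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Local tangent-plane coordinate reference
#'
#' A simple equirectangular projection around a reference latitude and
#' longitude: `x = (lon - lon0) * 111320 * cos(lat0)`,
#' `y = (lat - lat0) * 111320` (metres). Exactly invertible; adequate at
#' lake scale, where the package does all geometry in projected metres and
#' only the CSV boundary speaks lat/lon.
#'
#' @param lat0,lon0 reference point, decimal degrees
#' @return object of class `local_crs`
#' @export
local_crs <- function(lat0 = -38.08, lon0 = 176.27) {
  structure(list(lat0 = lat0, lon0 = lon0,
                 m_per_deg = 111320,
                 m_per_deg_lon = 111320 * cos(lat0 * pi / 180)),
            class = "local_crs")
}

#' @rdname local_crs
#' @param crs a `local_crs`
#' @param lon,lat coordinates to project
#' @export
lonlat_to_xy <- function(crs, lon, lat) {
  list(x = (lon - crs$lon0) * crs$m_per_deg_lon,
       y = (lat - crs$lat0) * crs$m_per_deg)
}

#' @rdname local_crs
#' @param x,y projected metres to unproject
#' @export
xy_to_lonlat <- function(crs, x, y) {
  list(lon = crs$lon0 + x / crs$m_per_deg_lon,
       lat = crs$lat0 + y / crs$m_per_deg)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' The standard plain-text raster interchange format (readable by GDAL and
#' QGIS): a 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `nodata_value`) followed by rows north to south. Values are
#' written at full double precision, so round trips are bit-exact.
#'
#' @param m numeric matrix (row 1 = north)
#' @param path output file
#' @param transform a [grid_transform()]
#' @param nodata nodata code, default -9999
#' @return (read) a matrix with a `transform` attribute
#' @export
write_ascii_grid <- function(m, path, transform, nodata = -9999) {
  stopifnot(is.matrix(m), inherits(transform, "grid_transform"),
            all(dim(m) == c(transform$nrow, transform$ncol)))
  m[is.na(m)] <- nodata
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", fmt_full(transform$x0)),
           paste("yllcorner", fmt_full(transform$y0 - nrow(m) * transform$cell)),
           paste("cellsize", fmt_full(transform$cell)),
           paste("nodata_value", fmt_full(nodata)))
  rows <- apply(m, 1L, function(r) paste(fmt_full(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, keys), collapse = ", "))
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != nr * nc) stop("ASCII grid body has wrong cell count")
  m <- matrix(body, nr, nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  tr <- grid_transform(vals["xllcorner"],
                       vals["yllcorner"] + nr * vals["cellsize"],
                       vals["cellsize"], nr, nc)
  attr(m, "transform") <- tr
  m
}

#' Write / read a scene time series
#'
#' A single-file plain-text container for the (time, y, x) scene cube:
#' a JSON header (grid transform, CRS note, variable list, CF-style
#' `flag_masks`/`flag_meanings`, config hash) followed by one block per
#' scene, time-ordered. Fills the role of the netCDF archive in a
#' text-only deliverable; chlorophyll and absorption values round-trip
#' bit-exactly and flag bits losslessly.
#'
#' @param scenes list of scenes sharing one grid
#' @param path output file
#' @param config_hash optional provenance tag stored in the header
#' @return (read) list of scenes with class `lake_scene`
#' @export
write_scene_series <- function(scenes, path, config_hash = NULL) {
  stopifnot(length(scenes) >= 1L)
  trs <- lapply(scenes, `[[`, "transform")
  if (!all(vapply(trs[-1L], same_grid, TRUE, b = trs[[1L]])))
    stop("scenes are on mixed grids")
  times <- vapply(scenes, function(s) as.numeric(s$timestamp), numeric(1))
  if (is.unsorted(times, strictly = TRUE))
    stop("scene times must be strictly increasing")
  tr <- trs[[1L]]
  vars <- intersect(c("chl", "a_pig", "a_det", "a_cdom"), names(scenes[[1L]]))
  vars <- vars[!vapply(scenes[[1L]][vars], is.null, TRUE)]
  meta <- list(format = "lakechl_series", version = 1L,
               nrow = tr$nrow, ncol = tr$ncol,
               transform = list(x0 = tr$x0, y0 = tr$y0, cell = tr$cell),
               crs = "local metric grid (north-up)",
               variables = c(vars, "flags"),
               flag_masks = unname(flag_bits()),
               flag_meanings = names(flag_bits()),
               config_hash = config_hash)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#LAKECHL_SERIES 1",
               paste0("#META ", jsonlite::toJSON(meta, auto_unbox = TRUE))),
             con)
  for (s in scenes) {
    writeLines(paste0("#SCENE ", format_utc(s$timestamp)), con)
    for (v in vars) {
      writeLines(paste0("#VAR ", v), con)
      writeLines(apply(s[[v]], 1L, function(r) paste(fmt_full(r), collapse = " ")),
                 con)
    }
    writeLines("#VAR flags", con)
    writeLines(apply(s$flags, 1L, function(r)
      paste(sprintf("%d", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_scene_series
#' @export
read_scene_series <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#LAKECHL_SERIES"))
    stop("not a lakechl scene series file: missing #LAKECHL_SERIES header")
  if (!startsWith(lines[2L], "#META "))
    stop("malformed series file: missing #META header")
  meta <- jsonlite::fromJSON(sub("^#META ", "", lines[2L]))
  nr <- meta$nrow; nc <- meta$ncol
  tr <- grid_transform(meta$transform$x0, meta$transform$y0,
                       meta$transform$cell, nr, nc)
  scene_starts <- which(startsWith(lines, "#SCENE "))
  if (length(scene_starts) == 0L) stop("series file contains no scenes")
  bounds <- c(scene_starts, length(lines) + 1L)
  scenes <- vector("list", length(scene_starts))
  for (k in seq_along(scene_starts)) {
    block <- lines[(bounds[k]):(bounds[k + 1L] - 1L)]
    ts <- parse_utc(sub("^#SCENE ", "", block[1L]))
    var_starts <- which(startsWith(block, "#VAR "))
    vb <- c(var_starts, length(block) + 1L)
    s <- list(timestamp = ts, transform = tr)
    for (m in seq_along(var_starts)) {
      vname <- sub("^#VAR ", "", block[var_starts[m]])
      body <- block[(vb[m] + 1L):(vb[m + 1L] - 1L)]
      if (length(body) != nr)
        stop("scene block for variable '", vname, "' has ", length(body),
             " rows, expected ", nr)
      vals <- scan(text = body, quiet = TRUE, na.strings = "NA")
      mat <- matrix(vals, nr, nc, byrow = TRUE)
      if (vname == "flags") {
        mat <- structure(matrix(as.integer(mat), nr, nc),
                         class = "quality_flags",
                         flag_masks = as.integer(meta$flag_masks),
                         flag_meanings = meta$flag_meanings)
      }
      s[[vname]] <- mat
    }
    class(s) <- "lake_scene"
    scenes[[k]] <- s
  }
  scenes
}

#' Write / read the in-situ sample CSV
#'
#' Schema: `lake, station_id, lat, lon, datetime, chl_mg_m3, source`, UTF-8
#' comma-separated, timestamps ISO 8601 UTC. Projected coordinates are
#' converted to lat/lon through the supplied [local_crs()] at this boundary
#' only. On read, rows with missing chlorophyll or coordinates are dropped
#' with line-numbered messages; unparseable dates are an error citing the
#' offending line.
#'
#' @param samples an `insitu_samples` data frame (with `x`, `y`)
#' @param path CSV path
#' @param crs a [local_crs()]
#' @return (read) an `insitu_samples` data frame with projected `x`, `y`
#' @export
write_insitu_csv <- function(samples, path, crs = local_crs()) {
  ll <- xy_to_lonlat(crs, samples$x, samples$y)
  out <- data.frame(lake = samples$lake, station_id = samples$station_id,
                    lat = fmt_full(ll$lat), lon = fmt_full(ll$lon),
                    datetime = format_utc(samples$datetime),
                    chl_mg_m3 = fmt_full(samples$chl_mg_m3),
                    source = samples$source)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_insitu_csv
#' @export
read_insitu_csv <- function(path, crs = local_crs()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("lake", "station_id", "lat", "lon", "datetime", "chl_mg_m3",
            "source")
  missing_col <- setdiff(need, names(d))
  if (length(missing_col))
    stop("in-situ CSV is missing column(s): ",
         paste(missing_col, collapse = ", "))
  if (nrow(d) == 0L) {
    out <- data.frame(lake = character(0), station_id = character(0),
                      x = numeric(0), y = numeric(0),
                      datetime = as.POSIXct(character(0), tz = "UTC"),
                      chl_mg_m3 = numeric(0), source = character(0))
    class(out) <- c("insitu_samples", "data.frame")
    return(out)
  }
  line_no <- seq_len(nrow(d)) + 1L  # header is line 1
  dt <- parse_utc(d$datetime)
  if (anyNA(dt))
    stop("malformed datetime on line(s) ",
         paste(line_no[is.na(dt)], collapse = ", "), " of ", basename(path))
  lat <- suppressWarnings(as.numeric(d$lat))
  lon <- suppressWarnings(as.numeric(d$lon))
  chl <- suppressWarnings(as.numeric(d$chl_mg_m3))
  bad <- is.na(lat) | is.na(lon) | is.na(chl)
  if (any(bad)) {
    message("dropping ", sum(bad), " row(s) with missing chl or ",
            "coordinates (line ", paste(line_no[bad], collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
    lat <- lat[!bad]; lon <- lon[!bad]; chl <- chl[!bad]; dt <- dt[!bad]
  }
  xy <- lonlat_to_xy(crs, lon, lat)
  out <- data.frame(lake = d$lake, station_id = d$station_id,
                    x = xy$x, y = xy$y, datetime = dt,
                    chl_mg_m3 = chl, source = d$source,
                    stringsAsFactors = FALSE)
  class(out) <- c("insitu_samples", "data.frame")
  out
}

#' Write / read the 3-band quantile-frequency composite
#'
#' One ESRI ASCII grid per band -- ordered near-median, near-lower-quartile,
#' near-upper-quartile -- plus the per-pixel denominator raster and a JSON
#' sidecar (band order, nodata, tolerance, coverage rule, denominator
#' rule). Fills the role of a 3-band GeoTIFF in a text-only deliverable.
#'
#' @param composite a `composite_frequency` (see [patchiness_composite()])
#' @param stem output path stem; files `<stem>_<band>.asc` and
#'   `<stem>.json` are written
#' @return (read) a `composite_frequency`
#' @export
write_composite_raster <- function(composite, stem) {
  stopifnot(inherits(composite, "composite_frequency"),
            !is.null(composite$transform))
  bands <- c(near_median = "band_q50", near_lower_quartile = "band_q25",
             near_upper_quartile = "band_q75")
  files <- character(0)
  for (b in names(bands)) {
    f <- paste0(stem, "_", b, ".asc")
    write_ascii_grid(composite[[bands[[b]]]], f, composite$transform)
    files <- c(files, basename(f))
  }
  fden <- paste0(stem, "_denominator.asc")
  write_ascii_grid(composite$denominator + 0, fden, composite$transform)
  meta <- list(format = "lakechl_composite", bands = names(bands),
               band_files = files, denominator_file = basename(fden),
               nodata = -9999, units = "percent",
               tolerance = composite$tolerance,
               coverage_threshold = composite$coverage_threshold,
               denominator_rule = composite$denominator_rule,
               n_scenes = composite$n_scenes)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_composite_raster
#' @export
read_composite_raster <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  if (!identical(meta$format, "lakechl_composite"))
    stop("not a lakechl composite sidecar: ", stem, ".json")
  dirn <- dirname(stem)
  grids <- lapply(meta$band_files, function(f) read_ascii_grid(file.path(dirn, f)))
  den <- read_ascii_grid(file.path(dirn, meta$denominator_file))
  tr <- attr(grids[[1L]], "transform")
  structure(list(band_q50 = grids[[1L]], band_q25 = grids[[2L]],
                 band_q75 = grids[[3L]], denominator = den,
                 n_scenes = meta$n_scenes,
                 denominator_rule = meta$denominator_rule,
                 tolerance = meta$tolerance,
                 coverage_threshold = meta$coverage_threshold,
                 transform = tr),
            class = "composite_frequency")
}

#' Write / read a lake polygon as GeoJSON
#'
#' @param poly a [lake_polygon()]
#' @param path output `.geojson` path
#' @param properties named list stored as feature properties
#' @return (read) a `lake_polygon`
#' @export
write_lake_geojson <- function(poly, path, properties = list()) {
  ring <- poly_coords(poly)
  closed <- if (nrow(ring)) rbind(ring, ring[1L, ]) else ring
  gj <- list(type = "FeatureCollection",
             features = list(list(
               type = "Feature",
               properties = properties,
               geometry = list(type = "Polygon",
                               coordinates = list(unname(closed))))))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_lake_geojson
#' @export
read_lake_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(gj$type, "FeatureCollection") || !length(gj$features))
    stop("not a GeoJSON FeatureCollection with features: ", path)
  geom <- gj$features[[1L]]$geometry
  if (!identical(geom$type, "Polygon"))
    stop("first feature is not a Polygon: ", path)
  co <- geom$coordinates
  ring <- if (is.array(co) && length(dim(co)) == 3L) co[1L, , ] else
    if (is.list(co)) co[[1L]] else co
  lake_polygon(ring)
}
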