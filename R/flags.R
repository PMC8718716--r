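#' Quality-flag vocabulary
#'
#' The pixel-classification and processor flags carried with every scene,
#' as an integer bitmask. Two flags are "positive" (they must be raised for
#' a pixel to be usable): `IDEPIX_WATER` and `SHORE_SHALLOW_BUFFER` (the
#' rasterized shoreline-and-shallow-water mask). The remaining nine are
#' "negative" contamination flags (clouds, cloud buffer and shadow, cirrus,
#' and the out-of-scope/out-of-range diagnostics of the IOP retrieval); any
#' one of them invalidates the pixel.
#'
#' @return named integer vector of bit values, in the fixed documented order
#' @export
flag_bits <- function() {
  nm <- c("IDEPIX_WATER", "IDEPIX_CLOUD", "IDEPIX_CLOUD_BUFFER",
          "IDEPIX_CLOUD_SHADDOW", "IDEPIX_CIRRUS_SURE",
          "RTOSA_OOS", "RTOSA_OOR", "RHOW_OOR", "RHOW_OOS", "IOP_OOR",
          "SHORE_SHALLOW_BUFFER")
  structure(as.integer(2^(seq_along(nm) - 1L)), names = nm)
}

#' @rdname flag_bits
#' @export
positive_flags <- function() c("IDEPIX_WATER", "SHORE_SHALLOW_BUFFER")

#' @rdname flag_bits
#' @export
negative_flags <- function() setdiff(names(flag_bits()), positive_flags())

#' Pack named boolean flag layers into a bitmask raster
#'
#' @param layers named list of logical matrices, one per raised flag; names
#'   must be from [flag_bits()]. Omitted flags are never raised.
#' @param dim raster dimensions, required when `layers` is empty
#' @return integer matrix of class `quality_flags` with `flag_masks` /
#'   `flag_meanings` attributes (CF-style)
#' @export
quality_flags <- function(layers = list(), dim = NULL) {
  bits <- flag_bits()
  if (length(layers)) {
    unknown <- setdiff(names(layers), names(bits))
    if (length(unknown))
      stop("unknown flag name(s): ", paste(unknown, collapse = ", "))
    dims <- unique(lapply(layers, base::dim))
    if (length(dims) != 1L) stop("flag layers disagree on raster dimensions")
    dim <- dims[[1L]]
  }
  if (is.null(dim)) stop("raster dimensions required when no layers given")
  m <- matrix(0L, dim[1L], dim[2L])
  for (nm in names(layers)) {
    lay <- layers[[nm]]
    lay[is.na(lay)] <- FALSE
    m <- m + bits[[nm]] * (lay != 0)
  }
  structure(m, class = "quality_flags",
            flag_masks = unname(bits), flag_meanings = names(bits))
}

#' Extract one flag layer from a bitmask
#'
#' @param flags a `quality_flags` bitmask
#' @param name one flag name
#' @return logical matrix, `TRUE` where the flag is raised
#' @export
flag_layer <- function(flags, name) {
  bits <- flag_meaning_bits(flags)
  if (!name %in% names(bits)) stop("flag layer absent from bitmask: ", name)
  out <- bitwAnd(as.integer(flags), bits[[name]]) != 0L
  matrix(out, nrow(flags), ncol(flags))
}

flag_meaning_bits <- function(flags) {
  meanings <- attr(flags, "flag_meanings")
  masks <- attr(flags, "flag_masks")
  if (is.null(meanings) || is.null(masks))
    stop("flags carry no flag_meanings/flag_masks metadata")
  structure(as.integer(masks), names = meanings)
}

#' Valid-pixel predicate
#'
#' A pixel is valid iff all positive flags (`IDEPIX_WATER`,
#' `SHORE_SHALLOW_BUFFER`) are raised and none of the nine negative flags
#' is raised.
#'
#' @param flags a `quality_flags` bitmask raster
#' @return logical matrix
#' @export
valid_pixel_mask <- function(flags) {
  bits <- flag_meaning_bits(flags)
  missing <- setdiff(names(flag_bits()), names(bits))
  if (length(missing))
    stop("missing flag layer(s): ", paste(missing, collapse = ", "))
  pos <- sum(bits[positive_flags()])
  neg <- sum(bits[negative_flags()])
  f <- as.integer(flags)
  ok <- bitwAnd(f, pos) == pos & bitwAnd(f, neg) == 0L
  matrix(ok, nrow(flags), ncol(flags))
}

#' Dilate a cloud mask by a square buffer
#'
#' Morphological dilation with a `(2 width + 1)` square (Chebyshev)
#' structuring element, used to derive `IDEPIX_CLOUD_BUFFER` from
#' `IDEPIX_CLOUD` in synthetic scenes. Default width 2 pixels.
#'
#' @param cloud_mask logical matrix
#' @param width buffer radius in pixels (>= 0)
#' @return logical matrix containing the input
#' @export
apply_cloud_buffer <- function(cloud_mask, width = 2L) {
  stopifnot(is.matrix(cloud_mask), width >= 0)
  width <- as.integer(width)
  if (width == 0L) return(cloud_mask != 0)
  m <- cloud_mask != 0
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (di in -width:width) {
    ri <- intersect(seq_len(nr), seq_len(nr) - di)
    for (dj in -width:width) {
      cj <- intersect(seq_len(nc), seq_len(nc) - dj)
      out[ri, cj] <- out[ri, cj] | m[ri + di, cj + dj]
    }
  }
  out
}
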