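#' Stain image container
#'
#' A `stain_image` wraps an H x W x 3 RGB raster together with its physical
#' scale (dots per inch) and a provenance string. Channel values live on the
#' 0--255 scale but are kept as doubles in memory; quantization to 8 bits
#' happens only when the image is written to disk.
#'
#' @param pixels numeric H x W x 3 array, values in `[0, 255]`.
#' @param dpi dots per inch of the raster; must be positive.
#' @param source_id provenance string (file name, generator tag, ...).
#' @return An object of class `stain_image`.
#' @export
stain_image <- function(pixels, dpi, source_id = "unknown") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (any(dim(pixels)[1:2] < 1L)) stop("image must have at least one pixel", call. = FALSE)
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0)
    stop("`dpi` must be a single positive number", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, dpi = dpi, source_id = source_id),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image> %d x %d px, %.0f dpi (%.1f x %.1f mm), source: %s\n",
              d[1], d[2], x$dpi, px_to_mm(d[1], x$dpi), px_to_mm(d[2], x$dpi),
              x$source_id))
  invisible(x)
}

#' Intensity map container
#'
#' Red color intensity of a stain image: 255 minus the Blue channel, the
#' quantity on which both the S-index and the C-index are defined. High
#' values mark pixels dense in red pigment (hemoglobin).
#'
#' @param values numeric H x W matrix on the 0--255 scale.
#' @param dpi dots per inch.
#' @param source_id provenance string.
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(values, dpi, source_id = "unknown") {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0)
    stop("`dpi` must be a single positive number", call. = FALSE)
  structure(list(values = values, dpi = dpi, source_id = source_id),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf("<intensity_map> %d x %d px, %.0f dpi, range [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values), x$dpi,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Convert an RGB stain image to a red color intensity map
#'
#' Red color intensity is defined as 255 minus the Blue channel value of each
#' pixel: the red hemoglobin pigment absorbs in the blue, so dense stains have
#' low Blue values and high intensity. Only the Blue channel is used; Red and
#' Green carry no signal for the indices.
#'
#' @param image a [stain_image()].
#' @return An [intensity_map()] with the same DPI.
#' @export
to_intensity <- function(image) {
  if (!inherits(image, "stain_image")) {
    if (is.array(image) && length(dim(image)) == 2L)
      stop("grayscale input has no Blue channel; supply an RGB stain_image",
           call. = FALSE)
    stop("`image` must be a stain_image", call. = FALSE)
  }
  intensity_map(255 - image$pixels[, , 3L], image$dpi, image$source_id)
}

#' Read a scanned sheet or single stain from disk
#'
#' Supports 8-bit RGB PNG and TIFF. DPI is taken from the `dpi` argument
#' (scanner resolution is rarely stored reliably in the file itself).
#'
#' @param path path to a `.png` or `.tif`/`.tiff` file.
#' @param dpi resolution the sheet was scanned at.
#' @return A [stain_image()].
#' @export
read_stain_image <- function(path, dpi) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = stop("JPEG input is not supported; convert to PNG or TIFF",
                call. = FALSE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 2L)
    stop("grayscale image has no Blue channel; an RGB scan is required",
         call. = FALSE)
  if (dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  stain_image(px * 255, dpi = dpi, source_id = basename(path))
}

#' Write a stain image as an 8-bit RGB PNG
#'
#' @param image a [stain_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_stain_image <- function(image, path) {
  stopifnot(inherits(image, "stain_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

# px <-> mm conversions (1 inch = 25.4 mm)
#' @rdname px_to_mm
#' @export
mm_to_px <- function(mm, dpi) mm * dpi / 25.4

#' Convert between pixels and millimetres at a given resolution
#' @param px,mm lengths in pixels / millimetres.
#' @param dpi dots per inch.
#' @return Converted length.
#' @export
px_to_mm <- function(px, dpi) px * 25.4 / dpi

# Run `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
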