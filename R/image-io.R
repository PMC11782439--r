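#' Read and write 8-bit RGB rasters
#'
#' `read_image()` reads a PNG or JPEG file into a `height x width x 3` array
#' of sRGB values in `[0, 1]` (8-bit values map to `value / 255`). Grayscale
#' images are expanded to three identical channels; an alpha channel is
#' dropped with a warning. `write_image()` quantises to 8 bits
#' (`round(value * 255)`) and writes PNG — lossless, so simulation outputs
#' are bit-stable across reruns. JPEG is accepted on input only.
#'
#' @param path File path. `read_image()` dispatches on the file extension.
#' @param image sRGB array in `[0, 1]`.
#' @return `read_image()`: an sRGB array. `write_image()`: `path`, invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      rlang::check_installed("jpeg", reason = "to read JPEG images")
      jpeg::readJPEG(path)
    },
    abort(sprintf("unsupported image format '.%s' (PNG or JPEG expected)", ext))
  )
  if (is.matrix(raw)) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) {
    warn(sprintf("%s: dropping alpha channel", basename(path)))
    raw <- raw[, , 1:3, drop = FALSE]
  }
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    abort(sprintf("%s: expected an RGB raster", basename(path)))
  }
  validate_image(raw, arg = basename(path))
  raw
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  validate_image(image)
  # explicit 8-bit quantisation so the on-disk contract is round(v * 255)
  q <- round(image * 255) / 255
  png::writePNG(q, target = path)
  invisible(path)
}

#' Display an image array
#'
#' Renders an sRGB array with [ggplot2::annotation_raster()], preserving the
#' aspect ratio. Convenience for inspecting fixtures and simulations.
#'
#' @param image sRGB array in `[0, 1]`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_image <- function(image, title = NULL) {
  validate_image(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(image, xmin = 0, xmax = w, ymin = 0, ymax = h) +
    ggplot2::xlim(0, w) +
    ggplot2::ylim(0, h) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = title) +
    ggplot2::theme_void()
}
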