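#' sRGB transfer functions
#'
#' Convert channel values between gamma-encoded sRGB and linear light using
#' the IEC 61966-2-1 piecewise transfer function (linear segment below
#' 0.04045 on decoding, exponent 2.4 above). Both functions are vectorised
#' and accept scalars, vectors or `height x width x 3` arrays; the shape of
#' the input is preserved.
#'
#' `srgb_to_linear()` requires values in `[0, 1]`. `linear_to_srgb()`
#' tolerates values outside `[0, 1]` (they arise transiently after cone-space
#' projection) and hard-clips its output to `[0, 1]`.
#'
#' @param x Numeric vector or array of channel values.
#' @return Numeric object of the same shape as `x`.
#' @examples
#' srgb_to_linear(0.5)            # 0.21404114
#' linear_to_srgb(srgb_to_linear(0.25))
#' @export
srgb_to_linear <- function(x) {
  validate_channels(x, require_unit = TRUE)
  out <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  restore_shape(out, x)
}

#' @rdname srgb_to_linear
#' @export
linear_to_srgb <- function(x) {
  validate_channels(x, require_unit = FALSE)
  x <- pmin(pmax(x, 0), 1)
  out <- ifelse(x <= 0.0031308, x * 12.92, 1.055 * x^(1 / 2.4) - 0.055)
  restore_shape(pmin(pmax(out, 0), 1), x)
}

restore_shape <- function(out, template) {
  if (!is.null(dim(template))) dim(out) <- dim(template)
  out
}

# Shared raster validation. Names the first offending pixel so callers can
# locate bad data in large images.
validate_channels <- function(x, require_unit = TRUE) {
  if (!is.numeric(x)) {
    abort("channel values must be numeric")
  }
  bad <- !is.finite(x)
  if (require_unit) bad <- bad | x < 0 | x > 1
  if (any(bad)) {
    idx <- which(bad)[1L]
    abort(sprintf(
      "invalid channel value %s at flat index %d%s",
      format(x[idx]), idx,
      if (require_unit) " (must be finite and in [0, 1])" else " (must be finite)"
    ))
  }
  invisible(x)
}

# Validate an H x W x 3 sRGB raster.
validate_image <- function(pixels, arg = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort(sprintf("%s must be a height x width x 3 numeric array", arg))
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    abort(sprintf("%s must have height >= 1 and width >= 1", arg))
  }
  validate_channels(pixels, require_unit = TRUE)
  invisible(pixels)
}
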