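#' Simulate dichromat perception of an sRGB image
#'
#' Transforms an image to how a dichromat would perceive it: decode sRGB to
#' linear light, map to LMS cone space, project onto the dichromat's 2-D
#' colour subspace, map back to linear RGB, hard-clip to gamut, re-encode.
#' `condition = "none"` returns the input unchanged (exact identity).
#'
#' @param image `height x width x 3` numeric array, sRGB in `[0, 1]`.
#' @param condition A condition from [cvd_conditions()].
#' @param model Model family passed to [build_dichromat_model()], or a
#'   prebuilt `cvd_model` object.
#' @param output `"srgb"` (default) for the finished image; `"linear_preclip"`
#'   for the projected linear-RGB pixels before gamut clipping, useful for
#'   inspecting the planar geometry of the simulated colour cloud.
#' @return Array with the same dimensions as `image`.
#' @examples
#' img <- array(runif(12), dim = c(2, 2, 3))
#' identical(simulate_cvd(img, "none"), img)
#' sim <- simulate_cvd(img, "tritanopia")
#' @export
simulate_cvd <- function(image, condition, model = c("brettel", "machado"),
                         output = c("srgb", "linear_preclip")) {
  output <- rlang::arg_match(output)
  if (inherits(condition, "cvd_model")) {
    mod <- condition
  } else {
    condition <- match_condition(condition)
    if (condition == "none") {
      validate_image(image)
      if (output == "linear_preclip") {
        return(srgb_to_linear(image))
      }
      return(image)
    }
    mod <- if (inherits(model, "cvd_model")) model else
      build_dichromat_model(condition, model)
  }
  validate_image(image)
  dims <- dim(image)

  lin <- srgb_to_linear(image)
  # pixels as a 3 x n matrix of linear RGB
  px <- rbind(as.vector(lin[, , 1]), as.vector(lin[, , 2]), as.vector(lin[, , 3]))
  sim <- simulate_pixels(px, mod)

  out <- array(0, dim = dims)
  out[, , 1] <- sim[1, ]
  out[, , 2] <- sim[2, ]
  out[, , 3] <- sim[3, ]
  if (output == "linear_preclip") out else linear_to_srgb(out)
}

# Core per-pixel-cloud transform on a 3 x n linear-RGB matrix; returns
# linear RGB before clipping.
simulate_pixels <- function(px, mod) {
  if (mod$family == "machado") {
    return(mod$rgb_matrix %*% px)
  }
  lms <- mod$rgb_to_lms %*% px
  if (mod$condition == "tritanopia") {
    side <- as.vector(mod$separating_normal %*% lms)
    proj <- lms
    first <- side >= 0 # ties go to the first (660 nm) half-plane
    if (any(first)) proj[, first] <- mod$projection_1 %*% lms[, first, drop = FALSE]
    if (any(!first)) proj[, !first] <- mod$projection_2 %*% lms[, !first, drop = FALSE]
  } else {
    proj <- mod$projection %*% lms
  }
  mod$lms_to_rgb %*% proj
}

#' Which tritanopia half-plane does each pixel fall in?
#'
#' @param image sRGB image array.
#' @param model A tritanopia `cvd_model` (Brettel family).
#' @return Integer matrix (height x width) of 1 (660 nm anchor half-plane)
#'   or 2 (485 nm anchor half-plane); ties count as 1.
#' @export
tritan_halfplane <- function(image, model = build_dichromat_model("tritanopia")) {
  stopifnot(inherits(model, "cvd_model"), model$condition == "tritanopia",
            model$family == "brettel")
  validate_image(image)
  lin <- srgb_to_linear(image)
  px <- rbind(as.vector(lin[, , 1]), as.vector(lin[, , 2]), as.vector(lin[, , 3]))
  side <- as.vector(model$separating_normal %*% (model$rgb_to_lms %*% px))
  matrix(ifelse(side >= 0, 1L, 2L), nrow = dim(image)[1])
}

#' Batch-simulate a directory of images
#'
#' Reads every PNG/JPEG in `input_dir`, applies [simulate_cvd()], and writes
#' the results to `output_dir` as PNG with the same basename. Unreadable
#' files are reported and skipped; the batch continues.
#'
#' @inheritParams simulate_cvd
#' @param input_dir,output_dir Directories of 8-bit RGB rasters.
#' @return Invisibly, the number of images written. An empty input directory
#'   gives a warning and count 0.
#' @export
batch_simulate <- function(input_dir, output_dir, condition,
                           model = c("brettel", "machado")) {
  condition <- match_condition(condition)
  files <- list.files(input_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files))]
  if (length(files) == 0L) {
    warn(sprintf("no PNG/JPEG files found in %s", input_dir))
    return(invisible(0L))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  mod <- if (condition == "none") "none" else build_dichromat_model(condition, model)
  written <- 0L
  for (f in files) {
    res <- tryCatch({
      img <- read_image(f)
      sim <- if (identical(mod, "none")) img else simulate_cvd(img, mod)
      out <- file.path(output_dir,
                       paste0(tools::file_path_sans_ext(basename(f)), ".png"))
      write_image(sim, out)
      TRUE
    }, error = function(e) {
      warn(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
      FALSE
    })
    if (res) written <- written + 1L
  }
  invisible(written)
}
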