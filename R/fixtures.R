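# Synthetic dermoscopic-like fixtures --------------------------------------
#
# Two-class lesion-on-skin images with class-conditional colour
# distributions: melanomas are multi-hued with a strong red component and an
# irregular outline; nevi are uniform light-brown/pink with a smooth
# outline. The generator is a pure function of (spec, seed), so fixture sets
# are bit-reproducible.

#' Specification for the synthetic fixture generator
#'
#' Defaults emulate a balanced 100-image study set at desk scale:
#' 50 images per class, 128 x 128 pixels, seed 20240427.
#'
#' @param n_per_class Images per class (>= 1).
#' @param image_size `c(height, width)` in pixels.
#' @param melanoma_palette Named list of sRGB component colours mixed within
#'   each melanoma lesion (dark brown, black, red, blue-gray).
#' @param nevus_palette Named list of the two sRGB endpoints blended into
#'   each nevus lesion base colour (light brown, pink).
#' @param background_mean Mean skin-tone sRGB.
#' @param background_jitter Per-image Gaussian sd of the skin tone.
#' @param noise_sd Per-channel additive Gaussian noise sd (clipped to gamut).
#' @param red_weight_range Range of the red component's mixing weight within
#'   melanoma lesions; this is what keeps the classes colour-separable.
#' @param redness_margin Required gap in mean lesion red-dominance
#'   (`R - (G + B) / 2`) between the classes; see [fixture_redness_gap()].
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A `cvd_fixture_spec` list.
#' @export
fixture_spec <- function(n_per_class = 50,
                         image_size = c(128, 128),
                         melanoma_palette = list(
                           dark_brown = c(0.32, 0.18, 0.10),
                           black = c(0.12, 0.09, 0.08),
                           red = c(0.74, 0.14, 0.15),
                           blue_gray = c(0.44, 0.48, 0.54)
                         ),
                         nevus_palette = list(
                           light_brown = c(0.58, 0.46, 0.38),
                           pink = c(0.80, 0.63, 0.65)
                         ),
                         background_mean = c(0.894, 0.741, 0.666),
                         background_jitter = 0.02,
                         noise_sd = 0.02,
                         red_weight_range = c(0.35, 0.60),
                         redness_margin = 0.08,
                         seed = 20240427) {
  stopifnot(n_per_class >= 1, length(image_size) == 2, all(image_size >= 8),
            noise_sd >= 0, background_jitter >= 0,
            length(red_weight_range) == 2, redness_margin >= 0)
  spec <- list(
    n_per_class = as.integer(n_per_class),
    image_size = as.integer(image_size),
    melanoma_palette = melanoma_palette,
    nevus_palette = nevus_palette,
    background_mean = background_mean,
    background_jitter = background_jitter,
    noise_sd = noise_sd,
    red_weight_range = red_weight_range,
    redness_margin = redness_margin,
    seed = as.integer(seed)
  )
  class(spec) <- "cvd_fixture_spec"
  spec
}

#' Generate a synthetic fixture dataset
#'
#' Writes `2 * n_per_class` PNGs under `out_dir/<label>/<id>.png` plus a
#' `manifest.json`, and returns the manifest. Identical (spec, seed) runs
#' produce byte-identical directories. Lesion masks are attached to the
#' returned manifest as the `"masks"` attribute (a named list of logical
#' matrices) for colour-statistics checks.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest tibble with attribute `"masks"`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), out_dir) {
  stopifnot(inherits(spec, "cvd_fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  ids <- c(sprintf("m_%03d", seq_len(spec$n_per_class) - 1L),
           sprintf("n_%03d", seq_len(spec$n_per_class) - 1L))
  labels <- rep(LABELS, each = spec$n_per_class)
  masks <- vector("list", length(ids))
  names(masks) <- ids
  paths <- character(length(ids))
  withr::with_seed(spec$seed, {
    for (i in seq_along(ids)) {
      gen <- generate_lesion_image(labels[i], spec)
      dest_dir <- file.path(out_dir, labels[i])
      dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
      paths[i] <- file.path(dest_dir, paste0(ids[i], ".png"))
      write_image(gen$image, paths[i])
      masks[[i]] <- gen$mask
    }
  })
  manifest <- new_manifest(ids, labels, paths, "none")
  manifest <- dplyr::arrange(manifest, .data$id)
  class(manifest) <- c("cvd_manifest", class(tibble::tibble()))
  write_manifest(manifest, file.path(out_dir, "manifest.json"),
                 relative_to = out_dir)
  attr(manifest, "masks") <- masks[manifest$id]
  manifest
}

# One lesion image: skin background + (ir)regular elliptical lesion +
# class-conditional colouring + additive Gaussian noise, clipped to gamut.
generate_lesion_image <- function(label, spec) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  bg <- pmin(pmax(spec$background_mean + stats::rnorm(3, 0, spec$background_jitter), 0), 1)
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3))

  cy <- h * stats::runif(1, 0.42, 0.58)
  cx <- w * stats::runif(1, 0.42, 0.58)
  r0 <- min(h, w) * stats::runif(1, 0.22, 0.30)
  aspect <- stats::runif(1, 0.75, 1.0)

  yy <- matrix(seq_len(h), nrow = h, ncol = w)
  xx <- matrix(seq_len(w), nrow = h, ncol = w, byrow = TRUE)
  dy <- (yy - cy) / aspect
  dx <- xx - cx
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  if (label == "melanoma") {
    # irregular outline: low-order radial perturbation (asymmetry cue)
    amp <- stats::runif(4, 0.04, 0.12)
    phase <- stats::runif(4, 0, 2 * pi)
  } else {
    amp <- stats::runif(4, 0, 0.015)
    phase <- stats::runif(4, 0, 2 * pi)
  }
  boundary <- r0 * (1 + Reduce(`+`, lapply(1:4, function(k)
    amp[k] * sin((k + 1) * theta + phase[k]))))
  mask <- r <= boundary

  if (label == "melanoma") {
    comps <- spec$melanoma_palette
    w_red <- stats::runif(1, spec$red_weight_range[1], spec$red_weight_range[2])
    others <- stats::runif(length(comps) - 1L)
    weights <- setNames(numeric(length(comps)), names(comps))
    weights["red"] <- w_red
    weights[names(comps) != "red"] <- (1 - w_red) * others / sum(others)
    # angular sectors sized by weight => multi-hued lesion
    rot <- stats::runif(1, 0, 2 * pi)
    t_ang <- ((theta + rot) %% (2 * pi)) / (2 * pi)
    breaks <- cumsum(weights)
    sector <- matrix(findInterval(t_ang, c(0, head(breaks, -1))), nrow = h)
    shade <- 1 - 0.10 * pmin(r / pmax(boundary, 1e-9), 1)
    for (ch in 1:3) {
      comp_vals <- vapply(comps, `[`, numeric(1), ch)
      plane <- img[, , ch]
      plane[mask] <- (comp_vals[sector] * shade)[mask]
      img[, , ch] <- plane
    }
  } else {
    mix <- stats::runif(1, 0.25, 0.75)
    base <- mix * spec$nevus_palette$light_brown + (1 - mix) * spec$nevus_palette$pink
    shade <- 1 - 0.05 * pmin(r / pmax(boundary, 1e-9), 1)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- (base[ch] * shade)[mask]
      img[, , ch] <- plane
    }
  }

  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask)
}

#' Red-dominance gap between fixture classes
#'
#' Computes, over the lesion masks attached by [generate_fixtures()], the
#' mean red-dominance `R - (G + B) / 2` of lesion pixels per class and
#' returns the melanoma-minus-nevus gap. Red dominance rather than the raw
#' red channel is used because a pale pink nevus has a *high* red channel
#' without being red; dominance captures the colour the CVD story turns on.
#'
#' @param manifest Manifest returned by [generate_fixtures()] (with the
#'   `"masks"` attribute).
#' @return Named list with per-class means and `gap`.
#' @export
fixture_redness_gap <- function(manifest) {
  masks <- attr(manifest, "masks")
  if (is.null(masks)) abort("manifest has no lesion masks; use generate_fixtures()")
  dominance <- function(row) {
    img <- read_image(manifest$path[row])
    m <- masks[[manifest$id[row]]]
    mean(img[, , 1][m]) - (mean(img[, , 2][m]) + mean(img[, , 3][m])) / 2
  }
  vals <- vapply(seq_len(nrow(manifest)), dominance, numeric(1))
  mel <- mean(vals[manifest$label == "melanoma"])
  nev <- mean(vals[manifest$label == "nevus"])
  list(melanoma = mel, nevus = nev, gap = mel - nev)
}
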