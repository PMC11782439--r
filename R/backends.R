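# Backends ------------------------------------------------------------------
#
# A backend is any function taking a composed message (see
# [compose_prompt()]) and returning `list(raw_text =, backend_id =)`.
# Transport failures are signalled with condition class
# `cvd_transport_error` and retried by [classify()]. Real vision-language
# API adapters plug in through the same contract (keyed response caching by
# `request_digest` is recommended); none is bundled, so the package runs
# fully offline.

#' Deterministic nearest-reference mock backend
#'
#' Implements the protocol's "identify the most similar image, use its
#' label" rule literally: the query is compared with every reference and the
#' nearest reference's label is returned, together with a templated
#' explanation naming the dominant hue word of the query's lesion region.
#' Ties go to the earliest reference in presentation order (melanoma class
#' first), so tied distances resolve to melanoma.
#'
#' Two similarity modes:
#' * `"mean_color"` (default): Euclidean distance between mean linear-RGB
#'   colours.
#' * `"histogram"`: intersection of per-channel 8-bin sRGB histograms
#'   (higher intersection = more similar).
#'
#' The backend is a pure function of the message contents; per-image
#' features are memoised by content digest.
#'
#' @param similarity `"mean_color"` or `"histogram"`.
#' @param bins Bins per channel for the histogram mode.
#' @param backend_id Identifier recorded in responses.
#' @return A backend function.
#' @export
backend_mock <- function(similarity = c("mean_color", "histogram"), bins = 8,
                         backend_id = NULL) {
  similarity <- rlang::arg_match(similarity)
  backend_id <- backend_id %||% paste0("mock-", similarity)
  cache <- new.env(parent = emptyenv())

  feature <- function(part) {
    key <- part$digest
    if (!is.null(cache[[key]])) return(cache[[key]])
    img <- part$image
    val <- if (similarity == "mean_color") {
      lin <- srgb_to_linear(img)
      c(mean(lin[, , 1]), mean(lin[, , 2]), mean(lin[, , 3]))
    } else {
      breaks <- seq(0, 1, length.out = bins + 1)
      n_px <- dim(img)[1] * dim(img)[2]
      unlist(lapply(1:3, function(ch) {
        tabulate(findInterval(img[, , ch], breaks, rightmost.closed = TRUE),
                 nbins = bins) / n_px
      }))
    }
    cache[[key]] <- val
    val
  }

  function(message) {
    stopifnot(inherits(message, "cvd_message"))
    refs <- purrr::keep(message$parts, function(p) p$kind == "reference")
    query <- purrr::detect(message$parts, function(p) p$kind == "query")
    if (length(refs) == 0L || is.null(query)) {
      abort("mock backend needs at least one reference and one query part")
    }
    qf <- feature(query)
    score <- purrr::map_dbl(refs, function(p) {
      rf <- feature(p)
      if (similarity == "mean_color") {
        sqrt(sum((qf - rf)^2)) # lower is better
      } else {
        -sum(pmin(qf, rf)) # negated intersection: lower is better
      }
    })
    best <- which(score == min(score))[1] # tie -> earliest in presentation order
    label <- refs[[best]]$label
    hue <- dominant_hue_word(query$image)
    raw_text <- sprintf(
      "%s. The query most closely matches a labeled %s reference; the lesion area shows predominantly %s coloration.",
      paste0(toupper(substring(label, 1, 1)), substring(label, 2)), label, hue)
    list(raw_text = raw_text, backend_id = backend_id)
  }
}

#' Scoring backends for harness validation
#'
#' `backend_oracle()` always answers the query's true label (looked up by id
#' in `manifest`); `backend_adversarial()` always answers the opposite.
#' These bound what the evaluation harness can report: a run with the oracle
#' must score accuracy 1, with the adversary accuracy 0 and exactly mirrored
#' confusion counts.
#'
#' @param manifest Manifest holding the true labels.
#' @return A backend function.
#' @export
backend_oracle <- function(manifest) {
  validate_manifest(manifest)
  labels <- setNames(manifest$label, manifest$id)
  function(message) {
    query <- purrr::detect(message$parts, function(p) p$kind == "query")
    lab <- labels[[query$id]]
    list(raw_text = paste0(lab, ". Oracle lookup of the recorded diagnosis."),
         backend_id = "oracle")
  }
}

#' @rdname backend_oracle
#' @export
backend_adversarial <- function(manifest) {
  validate_manifest(manifest)
  labels <- setNames(manifest$label, manifest$id)
  function(message) {
    query <- purrr::detect(message$parts, function(p) p$kind == "query")
    lab <- setdiff(LABELS, labels[[query$id]])[1]
    list(raw_text = paste0(lab, ". Deliberately inverted answer."),
         backend_id = "adversarial")
  }
}

#' Dominant hue word of a lesion region
#'
#' Estimates the background skin tone from a 2-pixel border frame, takes the
#' lesion region as pixels farther than 0.12 (Euclidean, sRGB) from that
#' background (falling back to a central disc when almost nothing stands
#' out), and maps the mean lesion colour to one of five hue words by fixed
#' HSV bands: low saturation is "gray"; the red hue sector splits into
#' "pink" (light, desaturated) versus "red"; warm mid hues are "brown";
#' cyan-to-blue hues are "blue"; magenta hues are "pink".
#'
#' @param image sRGB array.
#' @return One of `"red"`, `"pink"`, `"brown"`, `"blue"`, `"gray"`.
#' @export
dominant_hue_word <- function(image) {
  validate_image(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  border <- matrix(FALSE, h, w)
  bw <- min(2L, h, w)
  border[c(seq_len(bw), h - seq_len(bw) + 1L), ] <- TRUE
  border[, c(seq_len(bw), w - seq_len(bw) + 1L)] <- TRUE
  bg <- vapply(1:3, function(ch) stats::median(image[, , ch][border]), numeric(1))
  d2 <- (image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 + (image[, , 3] - bg[3])^2
  mask <- sqrt(d2) > 0.12
  if (mean(mask) < 0.01) {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask <- sqrt((yy - (h + 1) / 2)^2 + (xx - (w + 1) / 2)^2) <= min(h, w) / 4
  }
  mean_col <- vapply(1:3, function(ch) mean(image[, , ch][mask]), numeric(1))
  hsv <- grDevices::rgb2hsv(mean_col[1], mean_col[2], mean_col[3], maxColorValue = 1)
  hue <- hsv[1] * 360
  s <- hsv[2]
  v <- hsv[3]
  if (s < 0.12) return("gray")
  if (hue >= 345 || hue < 15) {
    if (v >= 0.65 && s < 0.6) return("pink") else return("red")
  }
  if (hue < 170) return("brown")
  if (hue < 290) return("blue")
  "pink"
}
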