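# Shared test fixtures. The small on-disk fixture set is generated once per
# test session and reused read-only by the tests that need files.

random_image <- function(h = 16, w = 16, seed = NULL) {
  gen <- function() array(stats::runif(h * w * 3), dim = c(h, w, 3))
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

uniform_image <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# a flat skin background with a centred square "lesion" of the given colour
lesion_image <- function(lesion_rgb, h = 24, w = 24,
                         bg_rgb = c(0.894, 0.741, 0.666)) {
  img <- uniform_image(bg_rgb, h, w)
  rows <- (h %/% 3):(2 * h %/% 3)
  cols <- (w %/% 3):(2 * w %/% 3)
  for (ch in 1:3) img[rows, cols, ch] <- lesion_rgb[ch]
  img
}

# session-cached small fixture set (files persist for the whole run)
tiny_fixture_env <- new.env(parent = emptyenv())

tiny_fixtures <- function() {
  if (is.null(tiny_fixture_env$manifest)) {
    dir <- file.path(tempdir(), "cvdfewshot-tiny-fixtures")
    spec <- fixture_spec(n_per_class = 6, image_size = c(32, 32), seed = 101)
    tiny_fixture_env$manifest <- generate_fixtures(spec, dir)
    tiny_fixture_env$spec <- spec
  }
  tiny_fixture_env$manifest
}

# an in-memory manifest (no files) for sampling-logic tests
fake_manifest <- function(n_mel, n_nev = n_mel) {
  ids <- c(sprintf("m_%03d", seq_len(n_mel)), sprintf("n_%03d", seq_len(n_nev)))
  tibble::tibble(
    id = ids,
    label = rep(c("melanoma", "nevus"), c(n_mel, n_nev)),
    path = file.path("unused", paste0(ids, ".png")),
    condition = "none"
  )
}

# build a task straight from arrays (no files)
array_task <- function(query_img, query_label, ref_imgs, ref_labels,
                       query_id = "q", k_per_class = 1, replicate = 0L) {
  n <- length(ref_imgs)
  query <- tibble::tibble(id = query_id, label = query_label,
                          path = "unused", condition = "none")
  refs <- tibble::tibble(
    id = sprintf("r%d", seq_len(n)), label = ref_labels,
    path = "unused", condition = "none"
  )
  ord <- order(match(refs$label, c("melanoma", "nevus")))
  few_shot_task(query, refs[ord, ], query_image = query_img,
                reference_images = ref_imgs[ord], k_per_class = k_per_class,
                replicate_index = replicate)
}

# a synthetic cvd_experiment wrapping hand-written prediction rows
fake_experiment <- function(predictions, n_repeats = max(predictions$replicate) + 1L,
                            threshold = 5L) {
  cfg <- experiment_config(n_repeats = n_repeats,
                           consensus_threshold = min(threshold, n_repeats))
  structure(list(config = cfg, predictions = predictions), class = "cvd_experiment")
}
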