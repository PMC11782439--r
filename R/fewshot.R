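# Few-shot protocol ---------------------------------------------------------
#
# Leave-one-out reference sampling, prompt composition against a versioned
# template, backend dispatch, and answer parsing. Backends are plain
# functions (message -> response list), so the proprietary endpoint the
# protocol was designed around and the offline mock are interchangeable.

PROMPT_TEMPLATE_VERSION <- "1"

CLASS_KEYWORDS <- list(
  melanoma = c("melanoma", "malignant"),
  nevus = c("nevus", "naevus", "benign")
)

prompt_instruction <- function(k_per_class) {
  sprintf(paste0(
    "You are shown %d labeled reference dermoscopic images (%d of melanoma, ",
    "%d of nevus), followed by one unlabeled query image. Compare the query ",
    "to the references, identify the most similar reference image, and use ",
    "its label for your prediction. Answer with exactly one word, melanoma ",
    "or nevus, followed by a brief explanation mentioning the color features ",
    "you used."),
    2L * k_per_class, k_per_class, k_per_class)
}

# stable content digest of a pixel array; honours a precomputed
# "content_digest" attribute so pipelines can cache hashing
image_digest <- function(image) {
  pre <- attr(image, "content_digest")
  if (!is.null(pre)) return(pre)
  digest::digest(list(dim(image), as.numeric(image)), algo = "xxhash64")
}

# deterministic integer derived from a seed and a string key, < 2^31
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (abs(as.numeric(seed)) %% 2147483647 + h * 7919) %% 2147483647
}

#' Sample leave-one-out few-shot references
#'
#' Draws `k_per_class` reference images per class, uniformly without
#' replacement, excluding the query itself. The draw is fully determined by
#' the manifest order, the query id, `k_per_class` and `seed`.
#'
#' @param manifest A manifest tibble containing the query.
#' @param query_id Id of the query image (excluded from the draw).
#' @param k_per_class References per class (default 2, the protocol's
#'   standard setting).
#' @param seed Integer seed.
#' @return The selected manifest rows, melanoma references first then nevus,
#'   each class in sampled order.
#' @export
sample_references <- function(manifest, query_id, k_per_class = 2, seed = 1) {
  validate_manifest(manifest)
  if (!query_id %in% manifest$id) {
    abort(sprintf("query id '%s' not found in manifest", query_id))
  }
  picks <- withr::with_seed(derive_seed(seed, query_id), {
    purrr::map(LABELS, function(lab) {
      pool <- manifest$id[manifest$label == lab & manifest$id != query_id]
      if (length(pool) < k_per_class) {
        abort(sprintf(
          "class '%s' has only %d non-query image(s); %d needed",
          lab, length(pool), k_per_class))
      }
      pool[sample.int(length(pool), k_per_class)]
    })
  })
  ids <- unlist(picks)
  out <- manifest[match(ids, manifest$id), , drop = FALSE]
  class(out) <- c("cvd_manifest", class(tibble::tibble()))
  out
}

#' Construct a few-shot classification task
#'
#' Bundles one query and its sampled references, with the pixel data and the
#' conditions each was simulated under. The query's true label travels with
#' the task for scoring but is never disclosed to the backend.
#'
#' @param query One-row manifest entry for the query.
#' @param references Manifest rows for the references (class-balanced).
#' @param query_image,reference_images sRGB arrays; if `NULL` they are read
#'   from the manifest paths.
#' @param k_per_class References per class.
#' @param condition_query,condition_refs Conditions the images carry.
#' @param replicate_index Zero-based replicate number.
#' @param seed Seed the references were sampled with.
#' @return A `cvd_task` object.
#' @export
few_shot_task <- function(query, references, query_image = NULL,
                          reference_images = NULL, k_per_class = 2,
                          condition_query = "none", condition_refs = "none",
                          replicate_index = 0L, seed = 1L) {
  stopifnot(nrow(query) == 1L)
  if (query$id %in% references$id) {
    abort(sprintf("query '%s' appears among its own references", query$id))
  }
  counts <- table(factor(references$label, levels = LABELS))
  if (!all(counts == k_per_class)) {
    abort(sprintf("expected %d references per class, got %s",
                  k_per_class, paste(counts, collapse = "/")))
  }
  if (is.null(query_image)) query_image <- read_image(query$path)
  if (is.null(reference_images)) {
    reference_images <- purrr::map(references$path, read_image)
  }
  structure(list(
    query = list(id = query$id, label = query$label, image = query_image),
    references = tibble::tibble(
      id = references$id, label = references$label, image = reference_images
    ),
    k_per_class = as.integer(k_per_class),
    condition_query = match_condition(condition_query),
    condition_refs = match_condition(condition_refs),
    replicate_index = as.integer(replicate_index),
    seed = seed
  ), class = "cvd_task")
}

#' Compose the multimodal few-shot message
#'
#' Renders a task into the ordered message the backend contract consumes:
#' the instruction text, the labeled references (melanoma examples first,
#' then nevus, each in sampled order), and the unlabeled query last. The
#' text comes from a versioned template; the request digest covers the
#' template version, the text and the image contents, so any change to
#' either invalidates cached responses.
#'
#' @param task A `cvd_task`.
#' @return A `cvd_message` list with elements `template_version`, `text`,
#'   `parts` (one per image) and `request_digest`.
#' @export
compose_prompt <- function(task) {
  stopifnot(inherits(task, "cvd_task"))
  parts <- purrr::pmap(
    list(task$references$id, task$references$label, task$references$image),
    function(id, label, image) {
      list(kind = "reference", id = id, label = label, image = image,
           digest = image_digest(image))
    }
  )
  parts <- c(parts, list(list(
    kind = "query", id = task$query$id, label = NULL,
    image = task$query$image, digest = image_digest(task$query$image)
  )))
  text <- prompt_instruction(task$k_per_class)
  msg <- list(
    template_version = PROMPT_TEMPLATE_VERSION,
    text = text,
    parts = parts
  )
  msg$request_digest <- digest::digest(
    list(PROMPT_TEMPLATE_VERSION, text,
         purrr::map_chr(parts, "digest"),
         purrr::map(parts, function(p) p$label %||% NA_character_)),
    algo = "xxhash64"
  )
  class(msg) <- "cvd_message"
  msg
}

#' Parse a backend's free-text answer
#'
#' Looks for a class keyword, case-insensitively, on token boundaries:
#' "melanoma"/"malignant" map to melanoma, "nevus"/"naevus"/"benign" to
#' nevus. `parse_status` is `"clean"` when the first token is a class
#' keyword (the prescribed format), `"recovered"` when a keyword appears
#' later, and `"failed"` when no keyword is found or both classes are
#' mentioned (contradictory answer).
#'
#' @param raw_text Backend answer text.
#' @return List with `predicted_label` (`NA` on failure), `explanation`,
#'   `parse_status`.
#' @export
parse_response <- function(raw_text) {
  if (!is.character(raw_text) || length(raw_text) != 1L || is.na(raw_text) ||
      !nzchar(trimws(raw_text))) {
    return(list(predicted_label = NA_character_, explanation = "",
                parse_status = "failed"))
  }
  tokens <- stringr::str_split(tolower(raw_text), "[^a-z]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  hits <- purrr::map(CLASS_KEYWORDS, function(kw) which(tokens %in% kw))
  matched <- names(hits)[purrr::map_int(hits, length) > 0]
  if (length(matched) != 1L) {
    # absent or contradictory
    return(list(predicted_label = NA_character_, explanation = trimws(raw_text),
                parse_status = "failed"))
  }
  first_hit <- min(hits[[matched]])
  if (first_hit == 1L) {
    expl <- stringr::str_remove(
      trimws(raw_text), stringr::regex("^[a-z]+[[:punct:]]*\\s*", ignore_case = TRUE))
    list(predicted_label = matched, explanation = trimws(expl),
         parse_status = "clean")
  } else {
    list(predicted_label = matched, explanation = trimws(raw_text),
         parse_status = "recovered")
  }
}

#' Classify one few-shot task through a backend
#'
#' Composes the prompt, dispatches it to the backend, and parses the
#' response. Transport errors (condition class `cvd_transport_error`) are
#' retried with exponential backoff; when retries are exhausted the
#' prediction is returned with `parse_status = "failed"` and the cause in
#' `note`. Any other backend error is a contract violation and propagates.
#'
#' @param task A `cvd_task`.
#' @param backend A backend function: `function(message) -> list` with at
#'   least `raw_text` and `backend_id`.
#' @param max_retries Retries after the first transport failure.
#' @param retry_wait Initial backoff in seconds (doubled per retry).
#' @return One-row tibble: `query_id`, `true_label`, `replicate`,
#'   `predicted_label`, `explanation`, `parse_status`, `backend_id`,
#'   `request_digest`, `ref_ids`, `note`.
#' @export
classify <- function(task, backend, max_retries = 2, retry_wait = 0.1) {
  stopifnot(inherits(task, "cvd_task"), is.function(backend))
  msg <- compose_prompt(task)
  response <- NULL
  failure <- NULL
  for (attempt in 0:max_retries) {
    response <- tryCatch(
      backend(msg),
      cvd_transport_error = function(e) {
        failure <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(response)) break
    if (attempt < max_retries) Sys.sleep(retry_wait * 2^attempt)
  }
  if (is.null(response)) {
    parsed <- list(predicted_label = NA_character_, explanation = "",
                   parse_status = "failed")
    backend_id <- NA_character_
    note <- sprintf("transport error after %d attempt(s): %s",
                    max_retries + 1L, failure)
  } else {
    if (!is.list(response) || is.null(response$raw_text)) {
      abort("backend contract violation: response must be a list with raw_text")
    }
    parsed <- parse_response(response$raw_text)
    backend_id <- response$backend_id %||% NA_character_
    note <- NA_character_
  }
  tibble::tibble(
    query_id = task$query$id,
    true_label = task$query$label,
    replicate = task$replicate_index,
    predicted_label = parsed$predicted_label,
    explanation = parsed$explanation,
    parse_status = parsed$parse_status,
    backend_id = backend_id,
    request_digest = msg$request_digest,
    ref_ids = paste(task$references$id, collapse = ","),
    note = note
  )
}

# signal a transport-level backend failure (retryable)
transport_error <- function(message) {
  rlang::abort(message, class = "cvd_transport_error")
}
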