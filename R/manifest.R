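new_manifest <- function(id, label, path, condition = "none") {
  out <- tibble::tibble(
    id = as.character(id),
    label = as.character(label),
    path = as.character(path),
    condition = as.character(condition)
  )
  class(out) <- c("cvd_manifest", class(tibble::tibble()))
  out
}

validate_manifest <- function(manifest) {
  required <- c("id", "label", "path", "condition")
  if (!is.data.frame(manifest) || !all(required %in% names(manifest))) {
    abort("manifest must be a data frame with columns id, label, path, condition")
  }
  if (anyDuplicated(manifest$id)) {
    abort(sprintf("duplicate image id(s): %s",
                  paste(unique(manifest$id[duplicated(manifest$id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(manifest$label), LABELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown label(s) %s; allowed labels: %s",
                  paste(bad, collapse = ", "), paste(LABELS, collapse = ", ")))
  }
  invisible(manifest)
}

#' Class counts and balance of a dataset manifest
#'
#' @param manifest A manifest tibble (see [load_manifest()]).
#' @return `class_counts()`: a named integer vector over the label set.
#'   `is_balanced()`: `TRUE` iff all class counts are equal.
#' @export
class_counts <- function(manifest) {
  validate_manifest(manifest)
  counts <- table(factor(manifest$label, levels = LABELS))
  setNames(as.integer(counts), names(counts))
}

#' @rdname class_counts
#' @export
is_balanced <- function(manifest) {
  counts <- class_counts(manifest)
  length(unique(counts)) == 1L
}

#' Load a labeled image collection from disk
#'
#' Expects the canonical layout `root_dir/<label>/<id>.png` with labels
#' drawn from `{melanoma, nevus}`. Entries are ordered lexicographically by
#' id so downstream sampling is deterministic.
#'
#' @param root_dir Directory with one subdirectory per class label.
#' @param condition Condition recorded for the entries (use the condition
#'   the images were simulated under, or `"none"` for originals).
#' @return A manifest tibble with columns `id`, `label`, `path`, `condition`.
#' @export
load_manifest <- function(root_dir, condition = "none") {
  condition <- match_condition(condition)
  if (!dir.exists(root_dir)) abort(sprintf("directory not found: %s", root_dir))
  subdirs <- basename(list.dirs(root_dir, recursive = FALSE))
  stray <- setdiff(subdirs, LABELS)
  if (length(stray) > 0) {
    abort(sprintf("unknown class directory '%s'; allowed labels: %s",
                  stray[1], paste(LABELS, collapse = ", ")))
  }
  rows <- purrr::map(LABELS, function(lab) {
    files <- list.files(file.path(root_dir, lab),
                        pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) {
      abort(sprintf("class '%s' has no images under %s", lab, root_dir))
    }
    ids <- tools::file_path_sans_ext(basename(files))
    ord <- order(ids)
    new_manifest(ids[ord], lab, files[ord], condition)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$id)
  class(out) <- c("cvd_manifest", class(tibble::tibble()))
  validate_manifest(out)
  out
}

#' Serialise a manifest to JSON and back
#'
#' The JSON round trip is lossless for the manifest columns. With
#' `relative_to`, image paths are stored relative to that directory (as
#' [generate_fixtures()] does), which keeps manifests portable and byte-
#' reproducible; `read_manifest()` resolves relative paths against the
#' manifest's own directory.
#'
#' @param manifest A manifest tibble.
#' @param path JSON file path.
#' @param relative_to Optional directory to relativise image paths against.
#' @return `write_manifest()`: `path` invisibly; `read_manifest()`: the
#'   manifest tibble.
#' @export
write_manifest <- function(manifest, path, relative_to = NULL) {
  validate_manifest(manifest)
  out <- manifest[, c("id", "label", "path", "condition")]
  if (!is.null(relative_to)) {
    prefix <- paste0(normalizePath(relative_to, winslash = "/"), "/")
    norm <- normalizePath(out$path, winslash = "/", mustWork = FALSE)
    rel <- startsWith(norm, prefix)
    out$path[rel] <- substring(norm[rel], nchar(prefix) + 1L)
  }
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(normalizePath(dirname(path), winslash = "/"),
                            df$path[rel])
  out <- new_manifest(df$id, df$label, df$path, df$condition)
  validate_manifest(out)
  out
}

#' Apply a CVD condition to every image in a manifest
#'
#' Runs [simulate_cvd()] over the collection and writes the results under
#' `out_dir/<label>/<id>.png`. Per-file failures are reported as warnings
#' and the batch continues; failed entries are dropped from the returned
#' manifest.
#'
#' @param manifest A manifest tibble.
#' @param condition Condition from [cvd_conditions()]; `"none"` copies the
#'   images unchanged.
#' @param out_dir Output directory.
#' @param model Model family for [build_dichromat_model()].
#' @return A new manifest with `condition` set to the applied condition.
#' @export
apply_condition <- function(manifest, condition, out_dir,
                            model = c("brettel", "machado")) {
  validate_manifest(manifest)
  condition <- match_condition(condition)
  mod <- if (condition == "none") NULL else build_dichromat_model(condition, model)
  ok <- logical(nrow(manifest))
  new_paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    dest_dir <- file.path(out_dir, manifest$label[i])
    dir.create(dest_dir, recursive = TRUE, showWarnings = FALSE)
    dest <- file.path(dest_dir, paste0(manifest$id[i], ".png"))
    res <- tryCatch({
      img <- read_image(manifest$path[i])
      sim <- if (is.null(mod)) img else simulate_cvd(img, mod)
      write_image(sim, dest)
      TRUE
    }, error = function(e) {
      warn(sprintf("apply_condition: skipping %s: %s",
                   manifest$id[i], conditionMessage(e)))
      FALSE
    })
    ok[i] <- res
    new_paths[i] <- dest
  }
  out <- manifest[ok, , drop = FALSE]
  out$path <- new_paths[ok]
  out$condition <- condition
  class(out) <- c("cvd_manifest", class(tibble::tibble()))
  out
}
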