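# Repeat-and-consensus evaluation harness -----------------------------------

#' Configuration for a repeated few-shot experiment
#'
#' The defaults mirror the standard protocol: two reference examples per
#' class, ten repeats, and a consensus threshold of five melanoma votes out
#' of ten. `condition_refs_mode = "matched"` simulates the references under
#' the query's condition (the adaptation under study);
#' `"non_simulated"` leaves them in original colour (the ablation control).
#'
#' @param condition_query Condition applied to every query image.
#' @param condition_refs_mode `"matched"` or `"non_simulated"`.
#' @param n_repeats Number of experiment repeats.
#' @param k_per_class References sampled per class and repeat.
#' @param consensus_threshold Melanoma votes (out of `n_repeats`) at or
#'   above which the consensus label is melanoma; defaults to a simple
#'   majority, `ceiling(n_repeats / 2)` (5 of 10 under the defaults).
#' @param base_seed Base seed; repeat `r` samples with seed `base_seed + r`.
#' @param backend_id Free-form backend tag recorded in results.
#' @return A `cvd_config` list with the resolved `condition_refs`.
#' @export
experiment_config <- function(condition_query = "none",
                              condition_refs_mode = c("matched", "non_simulated"),
                              n_repeats = 10,
                              k_per_class = 2,
                              consensus_threshold = NULL,
                              base_seed = 1,
                              backend_id = "mock") {
  condition_query <- match_condition(condition_query)
  condition_refs_mode <- rlang::arg_match(condition_refs_mode)
  consensus_threshold <- consensus_threshold %||% ceiling(n_repeats / 2)
  stopifnot(n_repeats >= 1, k_per_class >= 1, consensus_threshold >= 1)
  if (consensus_threshold > n_repeats) {
    abort("consensus_threshold must be <= n_repeats")
  }
  cfg <- list(
    condition_query = condition_query,
    condition_refs_mode = condition_refs_mode,
    condition_refs = if (condition_refs_mode == "matched") condition_query else "none",
    n_repeats = as.integer(n_repeats),
    k_per_class = as.integer(k_per_class),
    consensus_threshold = as.integer(consensus_threshold),
    base_seed = as.integer(base_seed),
    backend_id = backend_id
  )
  cfg$digest <- digest::digest(cfg[c(
    "condition_query", "condition_refs", "n_repeats", "k_per_class",
    "base_seed", "backend_id"
  )], algo = "xxhash64")
  class(cfg) <- "cvd_config"
  cfg
}

# image cache shared within one run: reads, simulates and hashes each
# (id, condition) at most once
image_provider <- function(manifest, conditions) {
  cache <- new.env(parent = emptyenv())
  models <- list()
  for (cond in setdiff(unique(conditions), "none")) {
    models[[cond]] <- build_dichromat_model(cond)
  }
  paths <- setNames(manifest$path, manifest$id)
  function(id, condition) {
    key <- paste0(id, "@", condition)
    if (!is.null(cache[[key]])) return(cache[[key]])
    base_key <- paste0(id, "@none")
    img <- cache[[base_key]]
    if (is.null(img)) {
      img <- read_image(paths[[id]])
      attr(img, "content_digest") <- image_digest(structure(img, content_digest = NULL))
      cache[[base_key]] <- img
    }
    if (condition != "none") {
      sim <- simulate_cvd(img, models[[condition]])
      attr(sim, "content_digest") <-
        image_digest(structure(sim, content_digest = NULL))
      cache[[key]] <- sim
      img <- sim
    }
    img
  }
}

prediction_log_line <- function(row, config_digest) {
  rec <- as.list(row)
  rec$config_digest <- config_digest
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' Read a JSONL prediction log
#'
#' @param path Log file written by [run_experiment()].
#' @return Tibble of prediction records.
#' @export
read_prediction_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  dplyr::bind_rows(purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[purrr::map_lgl(rec, is.null)] <- NA
    tibble::as_tibble(rec)
  }))
}

#' Run a repeated few-shot classification experiment
#'
#' For every query image in the manifest and every replicate `r` in
#' `0:(n_repeats - 1)`: sample leave-one-out references with seed
#' `base_seed + r`, apply the configured conditions (query always
#' `condition_query`; references matched or left non-simulated), classify
#' through the backend, and record the prediction. Per-repeat accuracy is
#' computed over parse-clean and recovered predictions; parse failures are
#' excluded from the denominator but counted and reported.
#'
#' When `log_path` is given, every prediction is appended to a JSONL log as
#' it completes; on rerun, (query, replicate) pairs already present in the
#' log under the same configuration digest are reused instead of recomputed,
#' so interrupted runs resume where they stopped.
#'
#' @param manifest A manifest tibble of original (non-simulated) images.
#' @param config An [experiment_config()].
#' @param backend A backend function (see [backend_mock()]).
#' @param log_path Optional JSONL log path.
#' @return A `cvd_experiment` object: `config`, `predictions` (tibble, one
#'   row per query x replicate), `per_repeat` (accuracy and failure counts),
#'   `summary` (mean and population sd of per-repeat accuracy).
#' @export
run_experiment <- function(manifest, config, backend, log_path = NULL) {
  validate_manifest(manifest)
  stopifnot(inherits(config, "cvd_config"), is.function(backend))
  provider <- image_provider(manifest,
                             c(config$condition_query, config$condition_refs))

  done <- tibble::tibble()
  if (!is.null(log_path) && file.exists(log_path)) {
    prior <- read_prediction_log(log_path)
    if (nrow(prior) > 0) {
      done <- dplyr::filter(prior, .data$config_digest == config$digest)
    }
  }
  done_keys <- if (nrow(done) > 0) paste(done$query_id, done$replicate) else character()

  con <- NULL
  if (!is.null(log_path)) {
    dir.create(dirname(log_path), recursive = TRUE, showWarnings = FALSE)
    con <- file(log_path, open = "a")
    on.exit(close(con), add = TRUE)
  }

  rows <- vector("list", nrow(manifest) * config$n_repeats)
  n <- 0L
  for (r in seq_len(config$n_repeats) - 1L) {
    for (i in seq_len(nrow(manifest))) {
      qid <- manifest$id[i]
      key <- paste(qid, r)
      n <- n + 1L
      if (key %in% done_keys) {
        rows[[n]] <- done[match(key, paste(done$query_id, done$replicate)), , drop = FALSE]
        next
      }
      refs <- sample_references(manifest, qid, config$k_per_class,
                                config$base_seed + r)
      task <- few_shot_task(
        query = manifest[i, , drop = FALSE],
        references = refs,
        query_image = provider(qid, config$condition_query),
        reference_images = purrr::map(refs$id, provider,
                                      condition = config$condition_refs),
        k_per_class = config$k_per_class,
        condition_query = config$condition_query,
        condition_refs = config$condition_refs,
        replicate_index = r,
        seed = config$base_seed + r
      )
      pred <- classify(task, backend)
      if (!is.null(con)) {
        writeLines(prediction_log_line(pred, config$digest), con)
        flush(con)
      }
      pred$config_digest <- config$digest
      rows[[n]] <- pred
    }
  }
  predictions <- dplyr::bind_rows(rows)

  per_repeat <- predictions |>
    dplyr::group_by(replicate = .data$replicate) |>
    dplyr::summarise(
      n_scored = sum(.data$parse_status != "failed"),
      n_failed = sum(.data$parse_status == "failed"),
      accuracy = mean(
        (.data$predicted_label == .data$true_label)[.data$parse_status != "failed"]
      ),
      .groups = "drop"
    )

  acc <- per_repeat$accuracy
  summary <- list(
    accuracy_mean = mean(acc),
    # population sd (ddof 0); a single repeat has sd 0 by convention
    accuracy_sd = if (length(acc) > 1) sqrt(mean((acc - mean(acc))^2)) else 0,
    n_repeats = config$n_repeats,
    n_queries = nrow(manifest),
    n_failed = sum(per_repeat$n_failed)
  )

  structure(list(
    config = config,
    manifest_labels = setNames(manifest$label, manifest$id),
    predictions = predictions,
    per_repeat = per_repeat,
    summary = summary
  ), class = "cvd_experiment")
}

#' @export
print.cvd_experiment <- function(x, ...) {
  cat(sprintf(
    "<cvd_experiment> query: %s, refs: %s | %d queries x %d repeats\n",
    x$config$condition_query, x$config$condition_refs,
    x$summary$n_queries, x$summary$n_repeats))
  cat(sprintf("  per-repeat accuracy %.3f +/- %.3f (%d parse failures)\n",
              x$summary$accuracy_mean, x$summary$accuracy_sd, x$summary$n_failed))
  invisible(x)
}

#' Majority-vote consensus over experiment repeats
#'
#' Counts, per query image, the melanoma votes among scoreable (parse-clean
#' or recovered) predictions and labels the image melanoma iff the votes
#' reach the threshold ("at least five out of ten" under the defaults).
#' Images with no scoreable replicate are excluded and reported.
#'
#' @param result A `cvd_experiment`.
#' @param threshold Vote threshold; defaults to the experiment's configured
#'   `consensus_threshold`.
#' @return A `cvd_consensus` object: `per_image` tibble (`query_id`,
#'   `true_label`, `n_votes`, `n_scored`, `consensus_label`), `accuracy`,
#'   `threshold`, `n_excluded`.
#' @export
consensus <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "cvd_experiment"))
  threshold <- threshold %||% result$config$consensus_threshold
  stopifnot(threshold >= 1)
  per_image <- result$predictions |>
    dplyr::filter(.data$parse_status != "failed") |>
    dplyr::group_by(query_id = .data$query_id, true_label = .data$true_label) |>
    dplyr::summarise(
      n_votes = sum(.data$predicted_label == POSITIVE_LABEL),
      n_scored = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      consensus_label = ifelse(.data$n_votes >= threshold, POSITIVE_LABEL, "nevus")
    ) |>
    dplyr::arrange(.data$query_id)

  all_ids <- unique(result$predictions$query_id)
  excluded <- setdiff(all_ids, per_image$query_id)
  if (length(excluded) > 0) {
    warn(sprintf("%d image(s) had no scoreable replicate and were excluded: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  structure(list(
    per_image = per_image,
    accuracy = mean(per_image$consensus_label == per_image$true_label),
    threshold = as.integer(threshold),
    n_excluded = length(excluded)
  ), class = "cvd_consensus")
}

#' @export
print.cvd_consensus <- function(x, ...) {
  cat(sprintf("<cvd_consensus> threshold >= %d votes | accuracy %.3f over %d images\n",
              x$threshold, x$accuracy, nrow(x$per_image)))
  invisible(x)
}

#' Confusion counts for binary melanoma-vs-nevus labels
#'
#' Melanoma is the positive class: `tp` are melanomas called melanoma, `fp`
#' nevi called melanoma, `tn` nevi called nevus, `fn` melanomas called
#' nevus.
#'
#' @param labels_true,labels_pred Equal-length label vectors over
#'   `{melanoma, nevus}`.
#' @return A `cvd_confusion` object with `tp`, `fp`, `tn`, `fn`, `n`,
#'   `accuracy`.
#' @export
confusion <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    abort(sprintf("label vectors differ in length (%d vs %d)",
                  length(labels_true), length(labels_pred)))
  }
  bad <- setdiff(unique(c(labels_true, labels_pred)), LABELS)
  if (length(bad) > 0) {
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  pos_t <- labels_true == POSITIVE_LABEL
  pos_p <- labels_pred == POSITIVE_LABEL
  structure(list(
    tp = sum(pos_t & pos_p),
    fp = sum(!pos_t & pos_p),
    tn = sum(!pos_t & !pos_p),
    fn = sum(pos_t & !pos_p),
    n = length(labels_true),
    accuracy = mean(labels_true == labels_pred)
  ), class = "cvd_confusion")
}

#' @export
print.cvd_confusion <- function(x, ...) {
  cat(sprintf("<cvd_confusion> TP %d FP %d TN %d FN %d | accuracy %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy))
  invisible(x)
}

#' Matched versus non-simulated reference ablation
#'
#' Fixes the CVD simulation of the query images and runs the experiment
#' twice: once with references simulated under the same condition (matched)
#' and once with original-colour references. Both arms share `base_seed`, so
#' the reference identities per (query, replicate) coincide and only their
#' colouring differs; this is asserted from the prediction records.
#'
#' @param manifest Manifest of original images.
#' @param condition Query condition (must not be `"none"`).
#' @param backend Backend function.
#' @param config Template [experiment_config()]; its `condition_query` and
#'   `condition_refs_mode` are overridden per arm.
#' @param log_dir Optional directory for per-arm JSONL logs.
#' @return A `cvd_ablation` object: `matched`, `non_simulated` (both
#'   `cvd_experiment`), `accuracy_difference` (matched minus non-simulated
#'   mean per-repeat accuracy).
#' @export
run_ablation <- function(manifest, condition, backend,
                         config = experiment_config(), log_dir = NULL) {
  condition <- match_condition(condition, allow_none = FALSE)
  stopifnot(inherits(config, "cvd_config"))
  arm_config <- function(mode) {
    experiment_config(
      condition_query = condition,
      condition_refs_mode = mode,
      n_repeats = config$n_repeats,
      k_per_class = config$k_per_class,
      consensus_threshold = config$consensus_threshold,
      base_seed = config$base_seed,
      backend_id = config$backend_id
    )
  }
  log_for <- function(mode) {
    if (is.null(log_dir)) NULL else
      file.path(log_dir, sprintf("%s_%s.jsonl", condition, mode))
  }
  matched <- run_experiment(manifest, arm_config("matched"), backend,
                            log_path = log_for("matched"))
  non_sim <- run_experiment(manifest, arm_config("non_simulated"), backend,
                            log_path = log_for("non_simulated"))

  key <- function(x) x$predictions[order(x$predictions$query_id,
                                         x$predictions$replicate),
                                   c("query_id", "replicate", "ref_ids")]
  if (!identical(key(matched), key(non_sim))) {
    abort("ablation arms drew different reference sets; shared-seed contract broken")
  }
  structure(list(
    condition = condition,
    matched = matched,
    non_simulated = non_sim,
    accuracy_difference = matched$summary$accuracy_mean - non_sim$summary$accuracy_mean
  ), class = "cvd_ablation")
}

#' @export
print.cvd_ablation <- function(x, ...) {
  cat(sprintf("<cvd_ablation> %s | matched %.3f vs non-simulated %.3f (diff %+.3f)\n",
              x$condition, x$matched$summary$accuracy_mean,
              x$non_simulated$summary$accuracy_mean, x$accuracy_difference))
  invisible(x)
}
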