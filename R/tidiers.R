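# broom-style tidiers and ggplot2 autoplot methods --------------------------

#' Tidy a repeated experiment into per-repeat rows
#'
#' @param x A `cvd_experiment`.
#' @param ... Unused.
#' @return Tibble with one row per repeat: `replicate`, `n_scored`,
#'   `n_failed`, `accuracy`.
#' @method tidy cvd_experiment
#' @export
tidy.cvd_experiment <- function(x, ...) {
  x$per_repeat
}

#' @rdname tidy.cvd_experiment
#' @return `glance()`: one-row tibble summarising the run.
#' @method glance cvd_experiment
#' @export
glance.cvd_experiment <- function(x, ...) {
  tibble::tibble(
    condition_query = x$config$condition_query,
    condition_refs = x$config$condition_refs,
    n_queries = x$summary$n_queries,
    n_repeats = x$summary$n_repeats,
    accuracy_mean = x$summary$accuracy_mean,
    accuracy_sd = x$summary$accuracy_sd,
    n_failed = x$summary$n_failed
  )
}

#' @method tidy cvd_consensus
#' @export
tidy.cvd_consensus <- function(x, ...) {
  x$per_image
}

#' @method glance cvd_consensus
#' @export
glance.cvd_consensus <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_images = nrow(x$per_image),
    n_excluded = x$n_excluded,
    consensus_accuracy = x$accuracy
  )
}

#' @method tidy cvd_confusion
#' @export
tidy.cvd_confusion <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fp", "tn", "fn"),
    count = c(x$tp, x$fp, x$tn, x$fn)
  )
}

#' @method glance cvd_confusion
#' @export
glance.cvd_confusion <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n,
    accuracy = x$accuracy,
    sensitivity = if (x$tp + x$fn > 0) x$tp / (x$tp + x$fn) else NA_real_,
    specificity = if (x$tn + x$fp > 0) x$tn / (x$tn + x$fp) else NA_real_
  )
}

#' @method tidy cvd_ablation
#' @export
tidy.cvd_ablation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$matched$per_repeat, arm = "matched"),
    dplyr::mutate(x$non_simulated$per_repeat, arm = "non_simulated")
  )
}

#' @method glance cvd_ablation
#' @export
glance.cvd_ablation <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    matched_accuracy = x$matched$summary$accuracy_mean,
    non_simulated_accuracy = x$non_simulated$summary$accuracy_mean,
    accuracy_difference = x$accuracy_difference
  )
}

#' @method tidy cvd_group_comparison
#' @export
tidy.cvd_group_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    n_a = x$n_a, n_b = x$n_b,
    t_statistic = x$t_statistic, df = x$df, p_value = x$p_value,
    method = x$method, zero_variance = x$zero_variance
  )
}

#' @method glance cvd_group_comparison
#' @export
glance.cvd_group_comparison <- function(x, ...) tidy.cvd_group_comparison(x, ...)

#' Plot per-repeat accuracies of an experiment
#'
#' @param object A `cvd_experiment`.
#' @param ... Unused.
#' @return A ggplot object: per-repeat accuracy columns with the run mean.
#' @method autoplot cvd_experiment
#' @export
autoplot.cvd_experiment <- function(object, ...) {
  df <- object$per_repeat
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replicate), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = object$summary$accuracy_mean,
                        linetype = "dashed", colour = "red") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "repeat", y = "accuracy",
      title = sprintf("query: %s, references: %s",
                      object$config$condition_query, object$config$condition_refs)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a matched-vs-non-simulated ablation
#'
#' @param object A `cvd_ablation`.
#' @param ... Unused.
#' @return A ggplot object: mean accuracy per arm with +/- 1 sd error bars.
#' @method autoplot cvd_ablation
#' @export
autoplot.cvd_ablation <- function(object, ...) {
  df <- tibble::tibble(
    arm = c("matched", "non_simulated"),
    accuracy = c(object$matched$summary$accuracy_mean,
                 object$non_simulated$summary$accuracy_mean),
    sd = c(object$matched$summary$accuracy_sd,
           object$non_simulated$summary$accuracy_sd)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$accuracy,
                                   fill = .data$arm)) +
    ggplot2::geom_col(width = 0.6, colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$accuracy - .data$sd,
                                        ymax = .data$accuracy + .data$sd),
                           width = 0.15) +
    ggplot2::scale_fill_manual(values = c(matched = "grey60",
                                          non_simulated = "white"),
                               guide = "none") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy",
                  title = sprintf("reference ablation under %s", object$condition)) +
    ggplot2::theme_minimal()
}

#' Plot per-replicate melanoma rates by colour-mention group
#'
#' @param object A `cvd_group_rates` tibble.
#' @param ... Unused.
#' @return A ggplot object: per-replicate points and group means.
#' @method autoplot cvd_group_rates
#' @export
autoplot.cvd_group_rates <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$rate)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "% melanoma predictions per replicate") +
    ggplot2::theme_minimal()
}
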