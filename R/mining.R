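# Explanation mining: RED / PINK colour-mention analysis --------------------

#' Default colour-mention keyword lists
#'
#' Matching is exact on lowercased tokens (split on any non-letter, so
#' hyphenated compounds like "red-brown" contribute both halves). Exact
#' token matching means "infrared" or "reduced" never count as red
#' mentions. Negated mentions ("no red areas") still count: the rule is
#' about the colour being mentioned, a documented simplification.
#'
#' @return Character vector of tokens.
#' @export
red_keywords <- function() c("red", "reddish", "redder", "reds")

#' @rdname red_keywords
#' @export
pink_keywords <- function() c("pink", "pinkish", "pinks")

#' Assign explanations to colour-mention groups
#'
#' An explanation is `"RED"` if any token matches the red keyword list,
#' regardless of pink mentions; `"PINK"` if it mentions pink without red;
#' otherwise `"NEITHER"`. The two named groups are therefore mutually
#' exclusive by construction. Empty or blank explanations map to
#' `"NEITHER"` with a warning.
#'
#' @param explanation Character vector of explanation texts.
#' @param red_words,pink_words Keyword token lists (see [red_keywords()]).
#' @return Character vector over `{"RED", "PINK", "NEITHER"}`.
#' @export
classify_mention <- function(explanation,
                             red_words = red_keywords(),
                             pink_words = pink_keywords()) {
  stopifnot(is.character(explanation))
  blank <- is.na(explanation) | !nzchar(trimws(explanation))
  if (any(blank)) {
    warn(sprintf("%d empty explanation(s) assigned to NEITHER", sum(blank)))
  }
  vapply(explanation, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return("NEITHER")
    tokens <- stringr::str_split(tolower(x), "[^a-z]+")[[1]]
    if (any(tokens %in% red_words)) "RED"
    else if (any(tokens %in% pink_words)) "PINK"
    else "NEITHER"
  }, character(1), USE.NAMES = FALSE)
}

#' Per-replicate melanoma-prediction rates by colour-mention group
#'
#' Partitions scoreable predictions into RED / PINK / NEITHER groups by
#' their explanations and computes, per group and replicate, the percentage
#' of melanoma predictions (`100 * melanoma / group size`). Replicates where
#' a group is empty are simply absent from the output (missing, not zero).
#'
#' @param predictions Prediction tibble (from a `cvd_experiment` or a log),
#'   with columns `replicate`, `predicted_label`, `explanation`,
#'   `parse_status`.
#' @inheritParams classify_mention
#' @return A tibble of class `cvd_group_rates`: `group`, `replicate`, `n`,
#'   `rate` (percent).
#' @export
group_rates <- function(predictions,
                        red_words = red_keywords(),
                        pink_words = pink_keywords()) {
  if (inherits(predictions, "cvd_experiment")) predictions <- predictions$predictions
  needed <- c("replicate", "predicted_label", "explanation", "parse_status")
  if (!all(needed %in% names(predictions))) {
    abort(sprintf("predictions must have columns: %s", paste(needed, collapse = ", ")))
  }
  scoreable <- dplyr::filter(predictions, .data$parse_status != "failed")
  if (nrow(scoreable) == 0) {
    warn("no scoreable predictions; returning empty rates")
    out <- tibble::tibble(group = character(), replicate = integer(),
                          n = integer(), rate = numeric())
    class(out) <- c("cvd_group_rates", class(out))
    return(out)
  }
  out <- scoreable |>
    dplyr::mutate(group = classify_mention(.data$explanation,
                                           red_words, pink_words)) |>
    dplyr::group_by(group = .data$group, replicate = .data$replicate) |>
    dplyr::summarise(
      n = dplyr::n(),
      rate = 100 * mean(.data$predicted_label == POSITIVE_LABEL),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group, .data$replicate)
  class(out) <- c("cvd_group_rates", class(out))
  out
}

#' Per-replicate rate vector for one group
#'
#' @param rates A [group_rates()] tibble.
#' @param group `"RED"`, `"PINK"` or `"NEITHER"`.
#' @return Numeric vector of per-replicate percentages.
#' @export
rates_vector <- function(rates, group) {
  rates$rate[rates$group == group]
}

#' Compare melanoma-prediction rates between two explanation groups
#'
#' Two-sample two-tailed t-test on per-replicate rates, unequal-variance
#' (Welch) by default; the pooled-variance variant is available with
#' `var_equal = TRUE`. Inputs may be two numeric rate vectors, or a
#' [group_rates()] tibble plus two group names.
#'
#' Degenerate inputs where both groups have zero variance cannot support a
#' t-test: identical means report `t = 0, p = 1`; different means report
#' `p = 0` with an infinite statistic, and `zero_variance = TRUE` flags the
#' case either way.
#'
#' @param a,b Numeric rate vectors, or (`a` only) a `cvd_group_rates` tibble.
#' @param group_a,group_b Group names used when `a` is a rates tibble.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `cvd_group_comparison` object with `t_statistic`, `df`,
#'   `p_value`, per-group means and sizes, and `zero_variance`.
#' @export
compare_groups <- function(a, b = NULL, group_a = "RED", group_b = "PINK",
                           var_equal = FALSE) {
  if (is.data.frame(a)) {
    rates <- a
    if (is.character(b)) {
      # positional call: compare_groups(rates, "RED", "PINK")
      group_b <- group_a
      group_a <- b
    }
    a <- rates_vector(rates, group_a)
    b <- rates_vector(rates, group_b)
  } else {
    group_a <- "a"
    group_b <- "b"
  }
  if (!is.numeric(a) || !is.numeric(b)) abort("rates must be numeric vectors")
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort(sprintf(
      "t-test undefined: need >= 2 replicate rates per group (got %d and %d)",
      length(a), length(b)))
  }
  zero_var <- var(a) == 0 && var(b) == 0
  if (zero_var) {
    if (mean(a) == mean(b)) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(mean(a) - mean(b)) * Inf
      p <- 0
    }
    df <- NA_real_
  } else {
    ht <- t.test(a, b, var.equal = var_equal)
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(
    group_a = group_a, group_b = group_b,
    mean_a = mean(a), mean_b = mean(b),
    n_a = length(a), n_b = length(b),
    t_statistic = t_stat, df = df, p_value = p,
    method = if (var_equal) "pooled" else "welch",
    zero_variance = zero_var
  ), class = "cvd_group_comparison")
}

#' @export
print.cvd_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<cvd_group_comparison> %s (%.1f%%, n=%d) vs %s (%.1f%%, n=%d)\n",
    x$group_a, x$mean_a, x$n_a, x$group_b, x$mean_b, x$n_b))
  cat(sprintf("  %s t = %.4g, df = %.4g, p = %.4g%s\n",
              x$method, x$t_statistic, x$df, x$p_value,
              if (x$zero_variance) " [zero-variance groups]" else ""))
  invisible(x)
}

#' Mine a prediction set for the colour-mention effect
#'
#' Convenience wrapper: computes [group_rates()] and, when both the RED and
#' PINK groups have at least two replicate rates, the RED-vs-PINK
#' comparison.
#'
#' @inheritParams group_rates
#' @param var_equal Passed to [compare_groups()].
#' @return List with `rates` and `comparison` (`NULL` when undefined).
#' @export
mine_explanations <- function(predictions,
                              red_words = red_keywords(),
                              pink_words = pink_keywords(),
                              var_equal = FALSE) {
  rates <- group_rates(predictions, red_words, pink_words)
  red <- rates_vector(rates, "RED")
  pink <- rates_vector(rates, "PINK")
  comparison <- if (length(red) >= 2 && length(pink) >= 2) {
    compare_groups(rates, "RED", "PINK", var_equal = var_equal)
  } else {
    NULL
  }
  list(rates = rates, comparison = comparison)
}
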