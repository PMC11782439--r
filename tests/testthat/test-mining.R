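test_that("colour mentions follow the red-dominates-pink rule", {
  expect_identical(classify_mention("irregular red streaks and pink areas"), "RED")
  expect_identical(classify_mention("uniform pink structureless area"), "PINK")
  expect_identical(classify_mention("blue-white veil over brown network"), "NEITHER")
  # token stems, not substrings: hyphens split, "infrared"/"reduced" never hit
  expect_identical(classify_mention("red-brown pigmentation"), "RED")
  expect_identical(classify_mention("infrared imaging reduced the glare"), "NEITHER")
  expect_identical(classify_mention("Reddish periphery"), "RED")
  expect_identical(classify_mention("PINKISH hue"), "PINK")
  # negations still count as mentions (documented simplification)
  expect_identical(classify_mention("no red areas visible"), "RED")
  expect_warning(out <- classify_mention(c("", "pink rim")), "empty")
  expect_identical(out, c("NEITHER", "PINK"))
})

test_that("custom keyword lists are honoured", {
  expect_identical(
    classify_mention("erythematous patch", red_words = c("red", "erythematous")),
    "RED")
})

test_that("RED and PINK partition any corpus disjointly", {
  withr::with_seed(31, {
    vocab <- c("red", "pink", "reddish", "pinkish", "brown", "blue", "gray",
               "network", "veil", "streaks", "infrared", "predominantly")
    corpus <- vapply(1:200, function(i)
      paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " "),
      character(1))
  })
  groups <- classify_mention(corpus)
  expect_identical(length(groups), 200L)
  expect_true(all(groups %in% c("RED", "PINK", "NEITHER")))
  has_red <- vapply(strsplit(tolower(corpus), "[^a-z]+"),
                    function(tk) any(tk %in% red_keywords()), logical(1))
  has_pink <- vapply(strsplit(tolower(corpus), "[^a-z]+"),
                     function(tk) any(tk %in% pink_keywords()), logical(1))
  expect_identical(groups == "RED", has_red)
  expect_identical(groups == "PINK", has_pink & !has_red)
})

test_that("group rates are per-replicate melanoma percentages", {
  preds <- tibble::tibble(
    replicate = 0L,
    predicted_label = c(rep("melanoma", 4), "melanoma", "melanoma", "nevus", "nevus"),
    explanation = c(rep("red streaks", 4), rep("pink rim", 4)),
    parse_status = "clean"
  )
  rates <- group_rates(preds)
  expect_identical(rates$rate[rates$group == "RED"], 100)
  expect_identical(rates$rate[rates$group == "PINK"], 50)
  expect_identical(rates$n, c(4L, 4L))
})

test_that("empty groups are missing rather than zero and counts are conserved", {
  preds <- tibble::tibble(
    replicate = rep(0:1, each = 3),
    predicted_label = rep(c("melanoma", "nevus", "nevus"), 2),
    explanation = c("red", "red", "pink", "brown", "brown", "gray"),
    parse_status = c(rep("clean", 5), "failed")
  )
  rates <- group_rates(preds)
  # replicate 1 has no RED or PINK rows at all
  expect_identical(nrow(rates[rates$group == "PINK" & rates$replicate == 1, ]), 0L)
  per_rep <- tapply(rates$n, rates$replicate, sum)
  scoreable <- table(preds$replicate[preds$parse_status != "failed"])
  expect_identical(as.integer(per_rep), as.integer(scoreable))
})

test_that("group rates match a hand tally over a real mock-run log", {
  man <- tiny_fixtures()
  res <- run_experiment(man, experiment_config(n_repeats = 3, base_seed = 12),
                        backend_mock())
  rates <- group_rates(res)
  df <- res$predictions[res$predictions$parse_status != "failed", ]
  for (row in seq_len(nrow(rates))) {
    g <- rates$group[row]
    r <- rates$replicate[row]
    members <- df[df$replicate == r &
                    classify_mention(df$explanation) == g, ]
    expect_identical(rates$n[row], nrow(members))
    expect_equal(rates$rate[row],
                 100 * sum(members$predicted_label == "melanoma") / nrow(members))
  }
})

test_that("the Welch comparison reproduces the textbook formulas", {
  a <- c(60, 70, 80, 90)
  b <- c(20, 30, 25, 35)
  got <- compare_groups(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  pooled <- compare_groups(a, b, var_equal = TRUE)
  want_pooled <- welch_oracle(a, b, var_equal = TRUE)
  expect_equal(pooled$t_statistic, want_pooled$t, tolerance = 1e-12)
  expect_equal(pooled$df, want_pooled$df, tolerance = 1e-12)
})

test_that("the comparison is symmetric up to the sign of t", {
  a <- c(55, 62, 71, 66, 59)
  b <- c(40, 38, 45, 52, 41)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$df, ba$df)
})

test_that("degenerate comparisons follow the documented policy", {
  expect_error(compare_groups(c(50), c(10, 20)), ">= 2 replicate rates")
  same <- compare_groups(c(50, 50, 50), c(50, 50, 50))
  expect_identical(same$t_statistic, 0)
  expect_identical(same$p_value, 1)
  expect_true(same$zero_variance)
  apart <- compare_groups(c(100, 100, 100), c(0, 0, 0))
  expect_identical(apart$p_value, 0)
  expect_identical(apart$t_statistic, Inf)
  expect_true(apart$zero_variance)
})

test_that("group_rates and compare_groups chain from a rates table", {
  preds <- tibble::tibble(
    replicate = rep(0:3, each = 4),
    predicted_label = rep(c("melanoma", "melanoma", "nevus", "nevus"), 4),
    explanation = rep(c("red", "red", "pink", "pink"), 4),
    parse_status = "clean"
  )
  rates <- group_rates(preds)
  cmp <- compare_groups(rates, "RED", "PINK")
  expect_identical(cmp$mean_a, 100)
  expect_identical(cmp$mean_b, 0)
  expect_true(cmp$zero_variance)
  out <- mine_explanations(preds)
  expect_identical(tidy(out$comparison)$p_value, 0)
})
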