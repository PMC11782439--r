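test_that("a run produces one record per query and replicate", {
  man <- tiny_fixtures()
  cfg <- experiment_config(n_repeats = 3, base_seed = 2)
  res <- run_experiment(man, cfg, backend_mock())
  expect_identical(nrow(res$predictions), nrow(man) * 3L)
  expect_identical(nrow(res$per_repeat), 3L)
  expect_true(all(res$per_repeat$accuracy >= 0 & res$per_repeat$accuracy <= 1))
})

test_that("a single-repeat run has sd zero by convention", {
  man <- tiny_fixtures()[c(1, 2, 7, 8), ]
  class(man) <- c("cvd_manifest", class(tibble::tibble()))
  res <- run_experiment(man, experiment_config(n_repeats = 1, k_per_class = 1),
                        backend_mock())
  expect_identical(nrow(res$predictions), 4L)
  expect_identical(res$summary$accuracy_sd, 0)
})

test_that("identical config and seed reproduce a byte-identical JSONL log", {
  man <- tiny_fixtures()
  cfg <- experiment_config("tritanopia", n_repeats = 2, base_seed = 5)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  run_experiment(man, cfg, backend_mock(), log_path = f1)
  run_experiment(man, cfg, backend_mock(), log_path = f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
})

test_that("interrupted runs resume from the log without recomputation", {
  man <- tiny_fixtures()
  cfg <- experiment_config(n_repeats = 2, base_seed = 8)
  full_log <- withr::local_tempfile(fileext = ".jsonl")
  full <- run_experiment(man, cfg, backend_mock(), log_path = full_log)

  part_log <- withr::local_tempfile(fileext = ".jsonl")
  lines <- readLines(full_log)
  writeLines(lines[1:10], part_log)
  calls <- 0L
  counting_backend <- local({
    inner <- backend_mock()
    function(message) {
      calls <<- calls + 1L
      inner(message)
    }
  })
  resumed <- run_experiment(man, cfg, counting_backend, log_path = part_log)
  expect_identical(calls, length(lines) - 10L)
  expect_identical(
    resumed$predictions[, c("query_id", "replicate", "predicted_label")],
    full$predictions[, c("query_id", "replicate", "predicted_label")]
  )
})

test_that("a perfect oracle scores accuracy 1 and an adversary accuracy 0", {
  man <- tiny_fixtures()
  cfg <- experiment_config(n_repeats = 2, base_seed = 4)
  res_o <- run_experiment(man, cfg, backend_oracle(man))
  expect_identical(res_o$summary$accuracy_mean, 1)
  cs <- consensus(res_o, threshold = 1)
  expect_identical(cs$accuracy, 1)

  res_a <- run_experiment(man, cfg, backend_adversarial(man))
  expect_identical(res_a$summary$accuracy_mean, 0)

  conf_o <- confusion(res_o$predictions$true_label, res_o$predictions$predicted_label)
  conf_a <- confusion(res_a$predictions$true_label, res_a$predictions$predicted_label)
  # label flipping mirrors the confusion counts: tp<->fn, tn<->fp
  expect_identical(conf_a$fn, conf_o$tp)
  expect_identical(conf_a$fp, conf_o$tn)
  expect_identical(conf_a$tp, conf_o$fn)
  expect_identical(conf_a$tn, conf_o$fp)
})

test_that("consensus follows the at-least-threshold rule over all vote counts", {
  n_rep <- 10L
  for (threshold in 1:n_rep) {
    labels <- vapply(0:n_rep, function(v) {
      preds <- tibble::tibble(
        query_id = "img", true_label = "melanoma",
        replicate = 0:(n_rep - 1L),
        predicted_label = rep(c("melanoma", "nevus"), c(v, n_rep - v)),
        parse_status = "clean"
      )
      res <- fake_experiment(preds, n_repeats = n_rep, threshold = threshold)
      consensus(res, threshold = threshold)$per_image$consensus_label
    }, character(1))
    expect_identical(labels, ifelse(0:n_rep >= threshold, "melanoma", "nevus"),
                     label = sprintf("threshold %d", threshold))
    # monotone: once melanoma, stays melanoma as votes increase
    expect_true(all(diff(labels == "melanoma") >= 0))
  }
})

test_that("consensus counts only scoreable replicates and reports exclusions", {
  preds <- tibble::tibble(
    query_id = rep(c("a", "b"), each = 4),
    true_label = rep(c("melanoma", "nevus"), each = 4),
    replicate = rep(0:3, 2),
    predicted_label = c("melanoma", "melanoma", "nevus", "melanoma",
                        NA, NA, NA, NA),
    parse_status = c(rep("clean", 3), "recovered", rep("failed", 4))
  )
  res <- fake_experiment(preds, n_repeats = 4L, threshold = 3L)
  expect_warning(cs <- consensus(res, threshold = 3), "excluded.*b")
  expect_identical(nrow(cs$per_image), 1L)
  expect_identical(cs$per_image$consensus_label, "melanoma")
  expect_identical(cs$n_excluded, 1L)
})

test_that("confusion counts match a brute-force tally and conserve totals", {
  expect_error(confusion(c("melanoma", "nevus"), "melanoma"), "length")
  all_right <- confusion(rep(LABELS, c(10, 10)), rep(LABELS, c(10, 10)))
  expect_identical(unclass(all_right)[c("tp", "fp", "tn", "fn")],
                   list(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  all_mel <- confusion(rep(LABELS, c(10, 10)), rep("melanoma", 20))
  expect_identical(unclass(all_mel)[c("tp", "fp", "tn", "fn")],
                   list(tp = 10L, fp = 10L, tn = 0L, fn = 0L))
  withr::with_seed(123, {
    for (i in 1:20) {
      truth <- sample(LABELS, 100, replace = TRUE)
      pred <- sample(truth)
      got <- confusion(truth, pred)
      want <- brute_confusion(truth, pred)
      expect_identical(unclass(got)[c("tp", "fp", "tn", "fn")], want)
      expect_identical(got$tp + got$fp + got$tn + got$fn, 100L)
    }
  })
})

test_that("ablation arms share reference identities and differ only in colouring", {
  man <- tiny_fixtures()
  ab <- run_ablation(man, "tritanopia", backend_mock(),
                     config = experiment_config(n_repeats = 2, base_seed = 6))
  key <- function(x) x$predictions[order(x$predictions$query_id,
                                         x$predictions$replicate), ]$ref_ids
  expect_identical(key(ab$matched), key(ab$non_simulated))
  expect_identical(ab$matched$config$condition_refs, "tritanopia")
  expect_identical(ab$non_simulated$config$condition_refs, "none")
  expect_equal(ab$accuracy_difference,
               ab$matched$summary$accuracy_mean -
                 ab$non_simulated$summary$accuracy_mean)
  expect_error(run_ablation(man, "none", backend_mock()), "none")
})

test_that("experiment invariants: accuracies bounded, predictions complete", {
  man <- tiny_fixtures()
  res <- run_experiment(man, experiment_config("protanopia", n_repeats = 2),
                        backend_mock())
  expect_true(all(res$predictions$query_id %in% man$id))
  expect_identical(sort(unique(res$predictions$replicate)), c(0L, 1L))
  expect_gte(res$summary$accuracy_mean, 0)
  expect_lte(res$summary$accuracy_mean, 1)
  # no task ever contained its own query
  for (i in seq_len(nrow(res$predictions))) {
    refs <- strsplit(res$predictions$ref_ids[i], ",")[[1]]
    expect_false(res$predictions$query_id[i] %in% refs)
  }
})
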